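Package: piwalk
Title: Noise Propagation in Path Integration and Directed Walks
Version: 0.1.0
Authors@R:
    person("Path Integration", "Maintainers", email = "maintainers@piwalk.example.org",
           role = c("aut", "cre"))
Description: Simulates home-vector maintenance by path integration under
    sensory input noise and update noise, for the four extended classes of
    spatial representation (allocentric/egocentric x static/dynamic
    vectorial) and an N-unit ring representation with static preferred
    directions and dynamic moduli.  Provides generators for allothetic and
    idiothetic directed walks and general biased elementary steps,
    closed-form per-step neural-record decompositions of the final home
    vector, ensemble Monte-Carlo statistics (mean error curves, endpoint
    moments, variance ordering, the finite mean-displacement limit of
    idiothetic walks), and a small command-line interface for reproducible
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
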