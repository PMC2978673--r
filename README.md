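# piwalk

Noise propagation in path integration and directed walks.

## The problem

Path integration (PI) is the continual summation of self-motion
displacements by which ants, bees, rodents and many other animals maintain
a **home vector** (HV) — their represented displacement from a reference
point.  Biological PI is noisy in two distinct places: every measured
heading or rotation carries an input error **δ**, and every update of the
stored state adds an update error **ε** to each state parameter that
changes.  How those errors accumulate depends dramatically on *how* the HV
is represented.  Spatial representations fall into four extended classes —
allocentric vs egocentric reference frame, crossed with static vs dynamic
vectorial axes — typified by allocentric Cartesian (AC), allocentric polar
(AP), egocentric Cartesian (EC) and egocentric polar (EP) coordinates, plus
ring-like networks of N static preferred directions with dynamic moduli.

`piwalk` is a simulator and analysis toolkit for this theory, aimed at
computational neuroscientists and movement modellers.  It implements:

* **Directed-walk generators** in physical space: allothetic directed walks
  (ADW, fresh compass errors each step), idiothetic directed walks (IDW,
  accumulating rotation errors), random turning walks, and general biased
  elementary steps with correlated turn/length noise.
* **Discrete-time HV update models** for AC, AP, EC, EP and the N-unit
  ring, with δ corrupting inputs and ε corrupting every updated parameter,
  a uniform decode contract, and per-step positional-error traces.
* **Closed-form neural records**: the post-hoc per-step decomposition of
  the final PI state.  For a straight physical walk of n steps the record
  of step m deviates by an angle that is `-(δ_m + … + δ_n)` for the
  egocentric static class, `ε_m + … + ε_n` for the allocentric dynamic
  class, `Σ(ε_k − δ_k)` for the egocentric dynamic class, `δ_m` alone for
  the allocentric static class, and `δ_1 + … + δ_m` when an allocentric
  static representation is fed only idiothetic rotation cues.  Summing the
  records reproduces the sequential simulation endpoint to machine
  precision — the package's central consistency oracle.
* **Ensemble statistics**: mean HV-error curves over shared random paths,
  endpoint moments, the finite mean-displacement limit of IDWs
  (`L·c/(1−c)` with `c = E[cos δ] = exp(−σ²/2)`), and the endpoint
  variance ordering IDW > uniform random walk > ADW.

The punchline the simulators expose: a straight walk in real space maps to
an ADW in representational space **only** for allocentric static vectorial
representations (AC-like, including rings of any N ≥ 3); every other class
behaves like an IDW in representational space and degrades rapidly — a
strong computational argument for allocentric static spatial codes in any
navigating nervous system.

## Worked example

```r
library(piwalk)

# a 100-step random turning walk (turn sd 0.1 rad), the ground truth
tr <- turning_walk(100, 1, 0.1, make_rng(42, "path-turns"))
tr
#> <real_trajectory n_steps=100 endpoint=(69.158, -63.791)>

# egocentric Cartesian PI with 5-degree input and update noise
run_pi(tr, "ec", noise_spec(input_mode = "direct_rotation"), rng = 42)
#> <hv_trace class=ec n_steps=100 final_pos_error=84.13>

# same walk, same noise magnitudes, allocentric Cartesian PI
run_pi(tr, "ac", noise_spec(), rng = 42)
#> <hv_trace class=ac n_steps=100 final_pos_error=2.447>

# the ensemble comparison (δ = ε = pi/36, turn sd 0.1, shared paths)
ensemble_hv_error(models = c("ap", "ep", "ac", "ec"),
                  n_paths = 250, n_steps = 1000, seed = 42)
#> <ensemble_curves models=ap,ep,ac,ec n_paths=250 n_steps=1000>
#>   ap   mean error at step 1000:  547.075 (SE 18.969)
#>   ep   mean error at step 1000:  563.183 (SE 18.435)
#>   ac   mean error at step 1000:    4.935 (SE 0.147)
#>   ec   mean error at step 1000:  485.009 (SE 18.011)
#>   mean radial distance R at step 1000: 533.717
```

After 100 steps the egocentric integrator is 84 length units off while the
allocentric Cartesian one is within 2.4 units of the truth; over 1000 steps
and 250 paths the AP/EP/EC mean errors (~500 units) are of the same order
as the walks' distance from home itself (R ≈ 534) — those HVs carry
essentially no positional information — while AC stays within ~5 units.
For comparison, `idw_limit(1, pi/36)` = 262.12 is the distance at which the
*mean* position of an idiothetic walk with 5° step noise saturates, however
long it walks.

## Command line

```sh
Rscript -e 'piwalk::cli_main()' simulate --model ac --steps 100 --seed 1 --delta-sd 0.0873 --out trace.csv
Rscript -e 'piwalk::cli_main()' fig4 --paths 250 --steps 1000 --seed 7 --out fig4_out
Rscript -e 'piwalk::cli_main()' record --class esvr --steps 10 --seed 2 --out records.csv
```

Subcommands: `simulate`, `record`, `stats`, `fig4`, `fixture`; a JSON
config file (`--config file.json`) supplies defaults that explicit flags
override.

## Documentation

The methods vignette (`vignettes/noise-in-path-integration.Rmd`) describes
the model classes, the noise contract, the neural-record algebra and its
sign/timing conventions, the synthetic-walk generators and what a green
test does and does not establish.
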