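---
title: "Noise in path integration: models, records, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise in path integration: models, records, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piwalk)
```

## The model

An agent takes discrete steps in the plane.  Step $k$ has true heading
$\theta_k$ (radians, allocentric zero along $+X$, counterclockwise
positive), turn $\Delta\theta_k = \theta_k - \theta_{k-1}$ (with
$\theta_0 = 0$ by convention) and length $L_k$.  A path integrator
maintains a home vector from noisy measurements of this motion.  Two
noise sources are modelled, both zero-mean Gaussian:

* **Input noise $\delta$** corrupts every measured heading
  ($\tilde\theta_k = \theta_k + \delta_k$) or rotation
  ($\Delta\tilde\theta_k = \Delta\theta_k + \delta_k$).  Even when the
  true rotation is zero the sensor reports $\delta_k$: the integrator
  cannot know nothing happened.
* **Update noise $\epsilon$** is added once per step to *each state
  parameter that is updated*: angular parameters get
  $\epsilon \sim N(0, \sigma_\epsilon^2)$ radians, linear parameters the
  equivalent in length units.

Five state representations implement the same task:

| class  | state                     | input      | extended class |
|--------|---------------------------|------------|----------------|
| `ac`   | $(U, V)$ allocentric Cartesian | heading   | allocentric static (ASVR) |
| `ap`   | $(r, \phi)$ allocentric polar  | heading   | allocentric dynamic (ADVR) |
| `ec`   | $(U', V')$ home in body frame  | rotation  | egocentric static (ESVR) |
| `ep`   | $(r', \phi')$ home bearing     | rotation  | egocentric dynamic (EDVR) |
| `ring` | $N$ static directions, dynamic moduli | heading | ring-like ASVR |

Egocentric axes: $+U'$ rostral, $+V'$ left; negative values mean backward
and rightward.  Allocentric states store the animal relative to home,
egocentric states home relative to the animal; `decode_hv()` always
returns the allocentric animal-relative-to-home estimate, mapping
egocentric states through the animal's *true* heading — the error metric,
not the model, sees ground truth, because a distance between the HV and
the true position is only defined in a common frame.

With all noise at zero the five models decode identical home vectors on
any trajectory (machine precision); every behavioural difference below is
noise-induced.

## Why the classes separate

The neural record of step $m$ after $n$ steps collects everything the
final state implies about that step.  For a straight physical walk the
record of step $m$ is $\Lambda_m(\cos\alpha_m, \sin\alpha_m)$ with

* ESVR: $\alpha_m = -(\delta_m + \dots + \delta_n)$ — each new rotation
  error turns the *whole* stored record, so errors accumulate in reverse
  temporal order; renumbering steps back-to-front
  (`renumber_reversed()`) exhibits a forward-accumulating idiothetic
  directed walk (IDW) driven by $-\delta$.
* ADVR: $\alpha_m = \epsilon_m + \dots + \epsilon_n$ — the angular update
  error adds to the *net* direction, rotating all previous steps: IDW in
  $\epsilon$.
* EDVR: $\alpha_m = \sum_{k=m}^{n}(\epsilon_k - \delta_k)$ — both
  mechanisms, signs opposed.
* ASVR: $\alpha_m = \delta_m$ — no coupling across steps: an allothetic
  directed walk (ADW).  With idiothetic input only, the heading estimate
  is an error integral and $\alpha_m = \delta_1 + \dots + \delta_m$: IDW
  again, which is why a compass matters even for a Cartesian code.

Directed-walk theory then fixes the phenomenology: an ADW's mean path is
the ideal path shrunk by $c = E[\cos\delta] = e^{-\sigma^2/2}$ with small,
linearly growing spread, while an IDW's mean displacement saturates at
$L\,c/(1-c)$ (with the first step already carrying an error) and its
endpoint variance exceeds even a uniform random walk's.  These closed
forms are not re-derived here; the package treats them as hypotheses and
verifies them against quadrature and Monte-Carlo oracles in the test
suite.

## Sign and timing conventions

Three conventions are genuinely open in a discrete-time implementation;
the package fixes them by requiring the closed-form records and the
sequential simulators to agree pathwise to $10^{-9}$ (the record-sum
oracle), which leaves no freedom:

* **Rotation sensing for EC/EP is end-of-step.**  The integrator state is
  updated when a step completes: step $k$'s translation is incorporated,
  then the rotation reading taken at the end of step $k$ (error
  $\delta_k$; the turn toward step $k+1$, zero-turn after the final step)
  rotates the whole record.  This reproduces
  $\alpha_m = -(\delta_m + \dots + \delta_n)$ exactly, including
  $\delta_1$ acting on step 1.  Sensing the turn *into* step $k$ instead
  would shift the index set to $m+1..n$ — asymptotically identical, but
  inconsistent with the record algebra this package exposes.  Decoding at
  step $k$ therefore uses the heading the animal faces after that
  reading.  For heading-integration input (the idiothetic ASVR variant)
  sensing is start-of-step, matching the forward index set
  $\delta_1..\delta_m$.
* **$\epsilon$ follows the geometric update** within a step
  (translate, then corrupt each updated parameter), so $\epsilon_m$
  already affects step $m$'s own record — the "sign of the update error
  is preserved" in the egocentric polar class, giving
  $\epsilon_k - \delta_k$ increments.
* **Step 1 carries an error.**  All walk generators give the first step a
  turn/heading error; the IDW mean-displacement partial sum is then
  $L(c + c^2 + \dots + c^n)$.  The alternative (error-free first step)
  adds $L(1-c)$ to every closed form; choosing one convention and testing
  against it matters more than which one.

## Numerical choices

* Angles wrap to $(-\pi, \pi]$; wrapping is idempotent, $2\pi$-periodic,
  and the boundary belongs to $+\pi$.
* Polar radii are moduli: after $r \mathrel{+}= \epsilon_r$ the radius is
  clipped at 0 and the event counted (`n_clipped` on the trace).  At the
  default noise scale clipping essentially never fires away from home.
* The ring decodes by least squares onto the two first harmonics of the
  preferred directions — the exact inverse of the noise-free encoding for
  any $N \ge 3$ evenly spaced units ($N = 2$ uses axes $0, \pi/2$ and is
  exactly AC).  Higher harmonics of the noise are simply ignored, which
  is what makes ring size nearly irrelevant.
* Step-length noise in `biased_step_walk()` is Gaussian truncated at 0 by
  redrawing (linear errors are secondary to angular ones; a sign-flipped
  step would be a different locomotor act).  Turn/length correlation uses
  a Gaussian copula.
* Random numbers come from named substreams (`make_rng(seed, id)`), so
  path turns, $\delta$ and $\epsilon$ can be toggled independently while
  every other draw stays identical; `sd = 0` still consumes draws to keep
  matched-noise comparisons aligned.  Reruns with the same configuration
  and seed are bit-identical.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `delta_sd` | $\pi/36$ | rad | 5° sensory error, the standard simulation condition |
| `eps_angular_sd` | $\pi/36$ | rad | update error of equal magnitude to input error |
| `eps_linear_sd` | $\pi/36$ | length | "5°-equivalent units" for linear parameters |
| `turn_sd` | 0.1 | rad | random-turn ground-truth paths of the ensemble experiment |
| `n_paths`, `n_steps` | 1000, 1000 | — | the reference ensemble; tests scale paths down to 250 and say so |
| `n_units` | 16 | — | illustrative ring size; results are N-insensitive (tested at N = 3) |

## What the generators emulate — and what they do not

The synthetic walks are the stated world of the theory: independent
Gaussian turns and (optionally) lengths, stationary noise, a point
animal, instantaneous readings.  Real locomotion has autocorrelated gait,
heteroscedastic and possibly biased sensors, von-Mises-like circular
error, and 3-D terrain, none of which is modelled.  A green test
therefore establishes internal consistency of theory and simulators under
Gaussian assumptions — not that any particular animal meets them.  The
class separation itself is robust to these details (it depends only on
*whether* angular errors accumulate), which is the theory's point, but
quantitative values such as the saturation radius are
Gaussian-specific.

## Operationalised criteria

Where the acceptance criteria name a qualitative property, the package
fixes a metric once, before measurement:

* "Variance" of an endpoint cloud is the trace of its covariance
  (rotation-invariant scalar); ordering is asserted with non-overlapping
  bootstrap 95% intervals.
* "No mean-displacement saturation" for rings: on straight true walks the
  mean decoded along-axis displacement must grow by a factor > 1.5 from
  step 500 to 1000 (an ADW doubles; a saturated IDW's ratio tends to 1).
* "Sublinear" growth of the mean radial distance $R$: log-log slope over
  steps 100–1000 below 0.9 (theory suggests ≈ 0.5–0.7 at the default
  parameters); ADW-like error growth: slope below 0.75 (≈ 0.5 expected).
* The factor-5 separation of AC from AP/EP/EC at step 1000 was first
  confirmed with a full 1000-path run (AC ≈ 4.6 units vs ≈ 530–565 for
  the rest, ratios > 100) before being asserted at the scaled-down 250
  paths.

## Known limitations

* No map-like (fixed-modulus, place-code) ASVR subclass, no attractor
  dynamics, no spiking noise, no steering/homing controller, no searching
  behaviour: the package simulates HV *maintenance* only.
* Closed-form moments are provided only for simple elementary steps;
  general biased steps are simulation-only.
* `compass_differenced` sensing is exposed as the special case it is
  (telescoping errors, bounded drift); no claims are made about its
  biological availability.
* Egocentric decoding consumes the true heading; models with a *noisy*
  self-alignment step would degrade further, so the reported egocentric
  errors are lower bounds.
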