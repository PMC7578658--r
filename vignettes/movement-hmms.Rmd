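---
title: "Covariate-driven movement HMMs: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-driven movement HMMs: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movestates)
```

## The model

`movestates` analyses regularised animal telemetry with an `N`-state hidden
Markov model. Each latent state `k` carries two state-dependent
distributions for the observables of one time step:

* **step length** `l_t ~ Gamma(mean mu_k, sd sigma_k)` in km per step, and
* **turning angle** `theta_t ~ von Mises(mean m_k, concentration kappa_k)`
  on `(-pi, pi]`.

States switch according to a row-stochastic transition matrix
`Gamma(z_t)` that depends on the covariates at the **start** of the step,
through a multinomial-logit link with the diagonal as reference:

```
eta_ij(z) = beta_0,ij + beta_1,ij z_1 + ... ,   eta_ii = 0
Gamma_ij(z) = exp(eta_ij(z)) / sum_j' exp(eta_ij'(z))
```

Three covariates are wired into the data-preparation pipeline, matching
the standard design for large-carnivore landscape analyses: a
standardised human-footprint index (`hfi_std`), a protected-area
indicator (`in_park`) and a denning-season indicator (`denning`, Julian
day inside an inclusive window, 160–220 by default). Any subset, or an
intercept-only model, can be fitted.

The likelihood is the scaled forward recursion, summed over individuals.
Missing observations (gaps in the regularised series, or steps below the
minimum-length filter) contribute an emission factor of 1 for the missing
component while transitions continue to advance, so the latent chain is
never broken by missingness. Each individual's initial state distribution
is the stationary distribution of `Gamma` at that individual's first
covariate row. This convention costs no extra parameters and is
well-defined in the presence of covariates; it is a modelling choice of
this package (the field's software packages differ in this detail), and
the parameter count `p = 4N + (1 + c) N(N - 1)` reflects it.

Two inferential summaries are built on the fitted model:

* **Stationary state probabilities** `delta(z)` solving
  `delta Gamma(z) = delta`, with 95% intervals by the delta method:
  numerical gradients of `delta_k` in the working parameters, covariance
  from the inverse observed Hessian of the negative log-likelihood, and a
  normal interval clamped to `[0, 1]`.
* **Pseudo-residuals**: the one-step-ahead forecast CDF of each observed
  component (a forward-weighted mixture of state CDFs) mapped through the
  standard-normal quantile. Under a correctly specified model these are
  standard normal; the angle CDF is taken on `(-pi, pi]` anchored at
  `-pi`.

## Data preparation

Raw fix tables (`id`, `timestamp`, `x_km`, `y_km`) are snapped to a fixed
time grid anchored at each individual's first fix (default 80 minutes,
the interval HMMs require to have constant spacing). A grid slot is
filled by the nearest fix within ±5 minutes; competing fixes are resolved
nearest-first and unmatched slots become missing positions. No
interpolation is performed — an invented position would contaminate both
the step and two turning angles.

Steps shorter than a minimum length (default 0.2 km) are treated as
resting artefacts and set missing rather than deleted, so the time grid
is preserved; turning angles on either side of a removed displacement are
also set missing because the heading through it is undefined. Zero- or
near-zero-length steps therefore never reach the gamma likelihood, which
needs no zero-inflation term.

Covariates are read at the step-start position (the cell containing it)
and timestamp. The footprint covariate is standardised by its mean and
population SD (divide by `n`) over the analysed records; the population
convention is arbitrary but fixed, and the stats are returned so
prediction grids can be mapped onto the same scale later.

Turning angles use the counterclockwise-positive sign convention, wrapped
to `(-pi, pi]`. Coordinates are planar kilometres; projecting raw
longitude/latitude is upstream of this package.

The pressure-score helper converts human population density to the
footprint index's population component: density capped at 1000 people per
km² (where the score saturates), then `3.333 * log10(density + 1)`. The
base-10 logarithm is forced by the stated saturation: at the cap the
score is `3.333 * log10(1001) ≈ 10`, the component's maximum.

## The synthetic-data generator

No telemetry is bundled with the package; every analysis stage is
exercised on synthetic data with the statistical structure the model
assumes.

* **Landscape**: a seeded, spatially autocorrelated footprint field (a
  west–east gradient plus Gaussian bumps) rescaled to the index range
  2–16 on a 1-km grid, with a protected-area mask covering the
  lowest-footprint half of the cells. The bump widths (6–18% of the grid
  extent) set the field's roughness; the true spatial covariance of a
  real footprint raster within a home range is not something we attempt
  to calibrate, so this knob is documented rather than tuned.
* **Tracks**: correlated random walks governed by an `hmm_spec`. At each
  step the covariates are read at the current position, the next state is
  drawn from the covariate-dependent transition row, and a step length
  and turning angle are drawn from the state's distributions; the heading
  accumulates turning angles from a uniform initial heading. Steps that
  would exit the grid are reflected at the boundary (with the heading
  mirrored so the angular dynamics are preserved) and flagged, because a
  reflected step's realised displacement no longer equals its drawn
  length. Reflection keeps tracks in-bounds without biasing the state
  dynamics; tests that compare drawn and recovered emissions simply use
  large landscapes where reflection is rare and skip flagged steps.
* **Resting**: a seeded fraction of steps is replaced by a sub-0.2-km
  displacement placed on the segment towards the original position (so it
  cannot leave the landscape), exercising the minimum-step filter.
* **Reference parameters**: `wild_dog_states()` provides the published
  three-state emission estimates for African wild dogs — per-state speeds
  (km/h) converted to step lengths by multiplying by the step duration
  (80 min → ×4/3 h), and circular SDs converted to von Mises
  concentrations by inverting `sd = sqrt(-2 log(I1(k)/I0(k)))`. The
  default generator uses nine individuals with ~1700 steps each, the
  scale of the motivating field study. Covariate slopes in
  `default_movement_spec()` are qualitative emulations (stronger
  footprint suppresses the fast state, park membership favours slower
  movement, denning favours fast excursions); no coefficient table is
  published to copy.

What the generator does **not** emulate: irregular fix failure patterns,
spatially heterogeneous GPS error, river or road barriers, home-range
tethering (beyond what state switching induces), and behavioural
responses to the boundary. Passing tests therefore demonstrate that the
estimators recover the truth under the model's own assumptions at
realistic sample sizes — not that a real data set satisfies those
assumptions.

## Fitting: numerical choices

The likelihood is maximised over an unconstrained working scale: log
step mean/SD, log concentration, free angle mean (wrapped on output) and
free transition coefficients. Gamma distributions are mean/SD
parameterised externally and shape/rate internally.

The optimiser is BFGS with analytic gradients, computed in compiled code
by a forward–backward pass: emission-parameter gradients use the Fisher
identity with smoothed state marginals, transition-coefficient gradients
use pair marginals against the multinomial-logit score, and the
dependence of the stationary initial distribution on the coefficients is
differentiated exactly through the linear system that defines it. The
gradient is verified against central finite differences in the test
suite.

Multiple starts guard against local maxima: step means start from a
quantile split of the observed steps, jittered ±20% log-normally, with
concentration 1 and near-balanced transition intercepts
(self-transition 0.8). Each start is explored for a capped number of BFGS
iterations (30 by default) and the best is polished to convergence
(relative tolerance 1e-9), where the Hessian is evaluated if requested.
Two fits from different start seeds on the same data agree to ~1e-4 in
log-likelihood in the test suite. Viterbi ties are broken toward the
lower state index for determinism, and fitted states are always
relabelled by increasing step mean, with the working parameter vector and
Hessian permuted consistently.

Degenerate situations are errors, not silent results: individuals with no
observed step, zero-variance footprint, a non-positive-definite Hessian
when intervals are requested (the message recommends more data or more
starts), and covariate rows missing from the step table. Missing
covariates at missing-position slots are filled by last observation
carried forward within the individual — some value is needed for the
transition matrix to advance across the gap, and the nearest known
position is the least informative choice.

## Verification strategy and problem sizes

The test suite checks the recursions against brute-force enumeration over
all `N^T` state sequences (up to `N = 3`, `T = 8`) to 1e-10, including
missing components, covariates, multiple individuals and label
permutations. Statistical behaviour is checked by simulation at sizes a
desk machine handles in minutes:

* recovery of the published per-state speeds (within 5%) and circular
  SDs (within 10%) in at least 9 of 10 replicates of 30 tracks × 500
  steps;
* AIC preferring three states over two in at least 18 of 20 replicates of
  a well-separated three-state scenario;
* 95% delta-method intervals for a stationary probability covering the
  truth 95 ± 5 times in 100 refits of a 10-track × 300-step scenario;
* pseudo-residuals passing a Kolmogorov–Smirnov test against the standard
  normal for a correctly specified fit (~5000 observations) and failing
  it for a deliberately misspecified single-state fit;
* ring-connection proportions non-decreasing in speed and concentration
  sweeps, and the fast/straight pattern out-connecting the slow/turning
  one with a two-proportion z well above 5.

## The connectivity simulator

`simulate_pattern()` strips the landscape and state machinery away to
isolate the mechanistic point: the distributions of speed and turning
angle alone determine how often a walker reaches distant places. Pattern
A (fast, shallow turns) and pattern B (slow, with a von Mises mixture
component centred at `pi` giving a high probability of sharp turns) are
qualitative emulations; connection is a pure distance threshold — an
individual connects if it ever reaches the ring radius within the
horizon. Both pattern parameter sets and the ring radius are free
arguments, and only ordering properties (not absolute proportions) are
asserted anywhere.

## Known limitations

* The HMM assumes exact, regular fixes; position error and irregular
  sampling are not modelled (continuous-time formulations would be the
  remedy and are out of scope).
* The minimum-step filter censors the smallest steps of genuinely slow
  states; at the published state-1 step scale a noticeable fraction of
  its steps fall below 0.2 km, so decoded state-1 occupancy is
  conservative on filtered data.
* Delta-method intervals are symmetric normal approximations clamped to
  `[0, 1]`; near the simplex boundary profile or bootstrap intervals
  would be preferable.
* The stationary-distribution summary describes long-run behaviour at
  frozen covariates; it is an interpretive device, not a prediction for
  a moving animal whose covariates change every step.
* Transition covariates enter additively on the logit scale;
  interactions are deliberately not modelled.
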