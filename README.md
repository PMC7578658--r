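# movestates

Covariate-driven hidden Markov models for animal movement, built for the
question conservation planners keep asking of telemetry data: *does the
human footprint change how an animal moves, and what does that imply for
connectivity between protected areas?*

A movement HMM describes a regularised GPS track as switches between `N`
latent behavioural states. Each state `k` emits the two observables of a
time step — step length `l_t ~ Gamma(μ_k, σ_k)` (km per step) and turning
angle `θ_t ~ von Mises(m_k, κ_k)` on `(−π, π]` — while the state sequence
follows a Markov chain whose transition matrix `Γ(z_t)` depends on the
covariates at the step's start through a multinomial logit with the
diagonal as reference:

    η_ij(z) = β·(1, z),   η_ii = 0,   Γ_ij(z) = exp(η_ij) / Σ_j' exp(η_ij')

The package covers the full analysis path:

* **Track preparation** — snapping fixes to a fixed time grid (80 min by
  default), step/turning-angle computation, a minimum-step filter
  (0.2 km) that marks resting artefacts missing without breaking the
  grid, covariate extraction from a footprint raster, protected-area mask
  and denning calendar, and footprint standardisation.
* **Inference** — maximum likelihood with analytic gradients and multiple
  starts, AIC selection of the number of states, Viterbi decoding,
  forward–backward state probabilities, stationary state probabilities
  `δ(z)` with delta-method 95% intervals, and pseudo-residual
  goodness-of-fit.
* **Synthetic data** — a seeded landscape generator (footprint field in
  the index range 2–16 plus park mask) and a track simulator with exactly
  the model's structure, including published three-state wild-dog
  emission parameters (`wild_dog_states()`) as a reference truth.
* **Connectivity** — a correlated-random-walk simulator showing how speed
  and turning-angle distributions alone drive the probability of reaching
  distant locations.

Everything takes and returns tibbles, so stages chain with the pipe, and
fitted models support `tidy()`, `glance()` and ggplot2-based plotting
(`plot_state_distributions()`, `autoplot()` on stationary curves,
`plot_decoded_map()`, `plot_qq_residuals()`).

## Worked example

Simulate a nine-pack scenario from the default three-state model (whose
emission parameters are the published wild-dog estimates and whose
footprint slope suppresses fast movement), prepare it exactly as real
fixes would be, and refit:

```r
library(movestates)

landscape <- make_landscape(seed = 1, n_cells_x = 80, n_cells_y = 80)
spec   <- default_movement_spec()
tracks <- simulate_tracks(spec, landscape, n_tracks = 9, n_steps = 600, seed = 1)
fixes  <- inject_resting(tracks, rest_prob = 0.1, seed = 2)

prep  <- prepare_steps(fixes, landscape)
steps <- prep$steps

sel <- model_select(steps, state_counts = c(2, 3),
                    covariates = c("hfi_std", "in_park", "denning"),
                    n_starts = 5, seed = 3)
sel$table
#> # A tibble: 2 × 5
#>   n_states  loglik n_params    aic delta_aic
#>      <int>   <dbl>    <int>  <dbl>     <dbl>
#> 1        2 -10527.       16 21086.      191.
#> 2        3 -10412.       36 20895.        0
```

AIC picks three states. Their estimated emissions recover the generating
slow / typical / fast structure (true step means 0.227, 1.467, 2.427 km;
the slow state's mean is inflated slightly because sub-0.2 km steps are
filtered):

```r
fit <- sel$fits$N3
fit$spec$emissions
#> # A tibble: 3 × 5
#>   state step_mean step_sd angle_mean angle_conc
#>   <int>     <dbl>   <dbl>      <dbl>      <dbl>
#> 1     1     0.266  0.0489    -0.121       0.220
#> 2     2     1.12   0.666      0.0634      0.528
#> 3     3     3.12   2.15      -0.0808      0.489
```

Decoding confidence and the footprint's effect on the long-run state mix
(inside the park, outside the denning season):

```r
assigned_state_summary(state_probs(fit, steps))
#> # A tibble: 1 × 2
#>   mean_prob sd_prob
#>       <dbl>   <dbl>
#> 1     0.756   0.197

stationary_curve(fit, tibble::tibble(hfi_std = c(-1, 0, 1),
                                     in_park = 1, denning = 0))
#> # A tibble: 9 × 7
#>   hfi_std in_park denning state delta  lower upper
#>     <dbl>   <dbl>   <dbl> <int> <dbl>  <dbl> <dbl>
#> 1      -1       1       0     1 0.253 0.207  0.298
#> 2      -1       1       0     2 0.352 0.264  0.440
#> 3      -1       1       0     3 0.395 0.309  0.482
#> 4       0       1       0     1 0.342 0.261  0.423
#> 5       0       1       0     2 0.384 0.289  0.479
#> 6       0       1       0     3 0.273 0.189  0.358
#> 7       1       1       0     1 0.447 0.302  0.593
#> 8       1       1       0     2 0.384 0.244  0.524
#> 9       1       1       0     3 0.169 0.0855 0.252
```

The stationary probability of the fast state falls from 0.40 to 0.17 as
the standardised footprint rises from −1 to +1 — the qualitative pattern
the generating model encodes — and each row of `δ` sums to 1.

An end-to-end run with artifacts on disk (CSV tables, JSON fit, PNG
figures, run log) is one call: `run_pipeline(default_config("out"))`.

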