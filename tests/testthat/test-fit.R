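test_that("a single-state fit recovers the closed-form MLE", {
  set.seed(31)
  n <- 4000
  step <- rgamma(n, (0.9 / 0.45)^2, scale = 0.45^2 / 0.9)
  angle <- rvonmises(n, 0.3, 1.8)
  angle[1] <- NA
  tb <- as_step_tbl(step, angle)
  fit <- fit_hmm(tb, n_states = 1, n_starts = 2, seed = 1)
  em <- fit$spec$emissions

  # gamma MLE: fitted mean equals the sample mean exactly
  expect_equal(em$step_mean, mean(step), tolerance = 1e-5)
  expect_equal(em$step_sd, sd(step), tolerance = 0.05)

  # von Mises MLE: mean direction is the circular sample mean, kappa solves
  # A(kappa) = mean resultant length
  a <- angle[!is.na(angle)]
  mdir <- atan2(mean(sin(a)), mean(cos(a)))
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  kap <- uniroot(function(k) besselI(k, 1, TRUE) / besselI(k, 0, TRUE) - rbar,
                 c(1e-6, 500), tol = 1e-10)$root
  expect_equal(em$angle_mean, mdir, tolerance = 1e-4)
  expect_equal(em$angle_conc, kap, tolerance = 1e-3)

  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params, tolerance = 1e-9)
  expect_equal(fit$n_params, 4L)
})

test_that("fits are stable across start seeds and ordered by step mean", {
  sp <- toy_spec_3()
  st <- sim_toy_steps(sp, n_tracks = 5, n_steps = 300, seed = 33)
  f1 <- fit_hmm(st, 3, n_starts = 4, seed = 101, hessian = FALSE)
  f2 <- fit_hmm(st, 3, n_starts = 4, seed = 202, hessian = FALSE)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-4)
  v1 <- c(f1$spec$emissions$step_mean, f1$spec$emissions$step_sd,
          f1$spec$emissions$angle_mean, f1$spec$emissions$angle_conc)
  v2 <- c(f2$spec$emissions$step_mean, f2$spec$emissions$step_sd,
          f2$spec$emissions$angle_mean, f2$spec$emissions$angle_conc)
  expect_lt(max(abs(v1 - v2)), 1e-3)
  expect_true(all(diff(f1$spec$emissions$step_mean) >= 0))
  expect_equal(f1$convergence, 0)
  expect_equal(nrow(f1$starts), 4)
})

test_that("parameter counts follow the transition model dimension", {
  expect_equal(n_hmm_params(3, 3), 12 + 4 * 6)
  expect_equal(n_hmm_params(2, 0), 8 + 2)
  expect_equal(n_hmm_params(1, 0), 4)
})

test_that("degenerate inputs are rejected with informative errors", {
  tb <- as_step_tbl(c(NA, NA, NA), c(NA, NA, NA))
  expect_error(fit_hmm(tb, 2, n_starts = 1), "observed step")
  obs <- toy_obs(10, seed = 35)
  tb2 <- as_step_tbl(obs$step, obs$angle)
  expect_error(fit_hmm(tb2, 2, covariates = "nope", n_starts = 1), "lacks")
})

test_that("model selection tabulates AIC and penalises overfitting", {
  # single-state data: the 2-state model rarely pays its parameter penalty
  wins <- 0L
  for (rep in 1:5) {
    set.seed(36 + rep)
    n <- 1500
    tb <- as_step_tbl(rgamma(n, 4, scale = 0.25), rvonmises(n, 0, 1.2))
    sel <- model_select(tb, state_counts = c(1, 2), n_starts = 3,
                        seed = 5 + rep, hessian = FALSE)
    expect_equal(sel$table$aic,
                 -2 * sel$table$loglik + 2 * sel$table$n_params,
                 tolerance = 1e-9)
    expect_equal(min(sel$table$delta_aic), 0)
    if (sel$best_n == 1) wins <- wins + 1L
  }
  expect_gte(wins, 3L)

  # 3-state data at a modest size: 3 states beat 2
  sp <- toy_spec_3()
  st <- sim_toy_steps(sp, n_tracks = 4, n_steps = 250, seed = 39)
  sel3 <- model_select(st, state_counts = c(2, 3), n_starts = 3, seed = 6,
                       hessian = FALSE)
  expect_equal(sel3$best_n, 3)
})

test_that("tidy and glance summarise a fit", {
  sp <- toy_spec_2()
  st <- sim_toy_steps(sp, n_tracks = 3, n_steps = 200, seed = 41)
  fit <- fit_hmm(st, 2, n_starts = 2, seed = 7, hessian = FALSE)
  td <- tidy(fit)
  expect_true(all(c("component", "state", "term", "estimate") %in% names(td)))
  expect_equal(sum(td$component == "emission"), 8)
  expect_equal(sum(td$component == "transition"), 2)
  gl <- glance(fit)
  expect_equal(gl$n_states, 2)
  expect_equal(gl$AIC, fit$aic)
})

test_that("the analytic likelihood gradient matches finite differences", {
  set.seed(53)
  spec <- hmm_spec(c(0.3, 1.2, 3.1), c(0.12, 0.5, 1), c(0, 0.3, -0.2),
                   c(0.6, 1.5, 4), beta = matrix(rnorm(12, 0, 0.4), 2, 6),
                   covariates = "z")
  n <- 60
  tb <- as_step_tbl(rgamma(n, 2, 1), rvonmises(n, 0, 1),
                    id = rep(c("a", "b"), each = n / 2), z = rnorm(n))
  tb$step_km[c(5, 20)] <- NA
  tb$angle_rad[c(1, 5, 33)] <- NA
  d <- build_hmm_data(tb, "z")
  f <- function(p) {
    u <- unpack_par(p, 3, 2)
    ms_nll(d$step0, d$lstep, d$cosang, d$sinang, d$sobs, d$aobs, d$Z,
           u$beta, u$mu, u$sigma, u$amean, u$kappa, d$bounds)
  }
  for (rep in 1:3) {
    par <- pack_par(spec)
    par <- par + rnorm(length(par), 0, 0.15)
    u <- unpack_par(par, 3, 2)
    res <- ms_nll_grad(d$step0, d$lstep, d$cosang, d$sinang, d$sobs, d$aobs,
                       d$Z, u$beta, u$mu, u$sigma, u$amean, u$kappa, d$bounds)
    expect_equal(res$nll, f(par), tolerance = 1e-12)
    num <- vapply(seq_along(par), function(q) {
      h <- 1e-6
      pp <- par; pp[q] <- pp[q] + h
      pm <- par; pm[q] <- pm[q] - h
      (f(pp) - f(pm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(res$grad - num)), 1e-4)
  }
})
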