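test_that("transition matrices follow the multinomial-logit link", {
  sp3 <- hmm_spec(c(0.2, 1, 3), c(0.1, 0.5, 1), rep(0, 3), rep(1, 3),
                  beta = matrix(0, 1, 6))
  g <- transition_matrix(sp3)
  expect_equal(g, matrix(1 / 3, 3, 3))

  # closed-form 2-state logistic: eta_12 = -log 3, eta_21 = 0
  sp2 <- hmm_spec(c(0.2, 1), c(0.1, 0.5), c(0, 0), c(1, 1),
                  beta = matrix(c(-log(3), 0), 1, 2))
  expect_equal(transition_matrix(sp2),
               matrix(c(0.75, 0.5, 0.25, 0.5), 2, 2), tolerance = 1e-12)

  set.seed(3)
  spz <- toy_spec_2("z")
  for (z in c(-2, 0, 1.7)) {
    g <- transition_matrix(spz, z)
    expect_equal(rowSums(g), c(1, 1), tolerance = 1e-12)
    expect_true(all(g > 0 & g < 1))
  }
  expect_error(transition_matrix(spz, NaN), "finite")
})

test_that("stationary distribution matches power iteration", {
  spz <- toy_spec_2("z")
  for (z in c(-1, 0.4)) {
    g <- transition_matrix(spz, z)
    d <- stationary_dist(g)
    p <- rep(1 / 2, 2)
    for (i in 1:400) p <- as.numeric(p %*% g)
    expect_equal(d, p, tolerance = 1e-12)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_equal(as.numeric(d %*% g), d, tolerance = 1e-12)
  }
  g3 <- transition_matrix(toy_spec_3())
  d3 <- stationary_dist(g3)
  p <- rep(1 / 3, 3)
  for (i in 1:600) p <- as.numeric(p %*% g3)
  expect_equal(d3, p, tolerance = 1e-12)
})

test_that("forward log-likelihood matches exhaustive enumeration", {
  # 2 states, T = 4, with a covariate and missing components
  spz <- toy_spec_2("z")
  obs <- toy_obs(4, seed = 1, miss_step = 3, miss_angle = c(1, 2))
  z <- c(-0.5, 0.2, 1.1, -1.3)
  Z <- cbind(1, z)
  oracle <- oracle_enumerate(spz, obs$step, obs$angle, Z)
  ll <- forward_loglik(spz, as_step_tbl(obs$step, obs$angle, z = z))
  expect_equal(ll, oracle$loglik, tolerance = 1e-10)

  # 3 states, T = 8, intercept-only
  sp3 <- toy_spec_3()
  obs3 <- toy_obs(8, seed = 2, miss_step = c(2, 6), miss_angle = c(1, 6))
  Z3 <- matrix(1, 8, 1)
  oracle3 <- oracle_enumerate(sp3, obs3$step, obs3$angle, Z3)
  ll3 <- forward_loglik(sp3, as_step_tbl(obs3$step, obs3$angle))
  expect_equal(ll3, oracle3$loglik, tolerance = 1e-10)

  # several individuals: log-likelihoods add
  both <- dplyr::bind_rows(
    as_step_tbl(obs3$step, obs3$angle, id = "a"),
    as_step_tbl(obs3$step[1:5], obs3$angle[1:5], id = "b")
  )
  oracle_b <- oracle_enumerate(sp3, obs3$step[1:5], obs3$angle[1:5],
                               matrix(1, 5, 1))
  expect_equal(forward_loglik(sp3, both),
               oracle3$loglik + oracle_b$loglik, tolerance = 1e-10)
})

test_that("a fully missing series has zero log-likelihood", {
  sp3 <- toy_spec_3()
  tb <- as_step_tbl(rep(NA_real_, 5), rep(NA_real_, 5))
  expect_equal(forward_loglik(sp3, tb), 0, tolerance = 1e-12)
})

test_that("a single state reduces to independent densities", {
  sp1 <- hmm_spec(0.8, 0.4, 0.1, 2)
  obs <- toy_obs(6, seed = 3, miss_step = 4, miss_angle = c(1, 5))
  shape <- (0.8 / 0.4)^2
  scale <- 0.4^2 / 0.8
  direct <- sum(dgamma(obs$step[!is.na(obs$step)], shape, scale = scale,
                       log = TRUE)) +
    sum(dvonmises(obs$angle[!is.na(obs$angle)], 0.1, 2, log = TRUE))
  expect_equal(forward_loglik(sp1, as_step_tbl(obs$step, obs$angle)),
               direct, tolerance = 1e-10)
})

test_that("the likelihood is invariant under state relabelling", {
  sp <- toy_spec_3()
  obs <- toy_obs(7, seed = 4)
  tb <- as_step_tbl(obs$step, obs$angle)
  ll <- forward_loglik(sp, tb)
  perm <- c(3, 1, 2)
  colof <- matrix(0L, 3, 3)
  cc <- 1L
  for (i in 1:3) for (j in 1:3) if (i != j) { colof[i, j] <- cc; cc <- cc + 1L }
  colmap <- integer(6)
  for (a in 1:3) for (b in 1:3) if (a != b)
    colmap[colof[a, b]] <- colof[perm[a], perm[b]]
  em <- sp$emissions
  sp_perm <- hmm_spec(em$step_mean[perm], em$step_sd[perm],
                      em$angle_mean[perm], em$angle_conc[perm],
                      beta = sp$beta[, colmap, drop = FALSE])
  expect_equal(forward_loglik(sp_perm, tb), ll, tolerance = 1e-10)
})

test_that("Viterbi and smoothed marginals match enumeration", {
  spz <- toy_spec_2("z")
  obs <- toy_obs(5, seed = 6, miss_step = 2, miss_angle = c(1, 4))
  z <- c(0.3, -0.8, 0.1, 1.2, -0.4)
  oracle <- oracle_enumerate(spz, obs$step, obs$angle, cbind(1, z))
  tb <- as_step_tbl(obs$step, obs$angle, z = z)
  fit <- list(spec = spz, covariates = "z")
  class(fit) <- "move_hmm"
  dec <- state_probs(fit, tb)
  expect_equal(dec$viterbi_state, oracle$viterbi)
  expect_equal(unname(as.matrix(dec[, c("prob_1", "prob_2")])),
               oracle$marginals, tolerance = 1e-10)
  expect_equal(rowSums(as.matrix(dec[, c("prob_1", "prob_2")])),
               rep(1, 5), tolerance = 1e-9)

  sp3 <- toy_spec_3()
  obs3 <- toy_obs(6, seed = 7, miss_angle = c(1, 3))
  oracle3 <- oracle_enumerate(sp3, obs3$step, obs3$angle, matrix(1, 6, 1))
  fit3 <- list(spec = sp3, covariates = character())
  class(fit3) <- "move_hmm"
  tb3 <- as_step_tbl(obs3$step, obs3$angle)
  dec3 <- state_probs(fit3, tb3)
  expect_equal(dec3$viterbi_state, oracle3$viterbi)
  expect_equal(unname(as.matrix(dec3[, paste0("prob_", 1:3)])),
               oracle3$marginals, tolerance = 1e-10)
})

test_that("a single-state decode assigns state 1 everywhere", {
  sp1 <- hmm_spec(0.8, 0.4, 0, 1)
  fit1 <- list(spec = sp1, covariates = character())
  class(fit1) <- "move_hmm"
  obs <- toy_obs(5, seed = 8)
  dec <- state_probs(fit1, as_step_tbl(obs$step, obs$angle))
  expect_equal(dec$viterbi_state, rep(1L, 5))
  expect_equal(dec$prob_1, rep(1, 5))
})
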