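# Brute-force oracles for small HMMs: enumerate all N^T state sequences.
# Independent of the package's forward/Viterbi/forward-backward code paths:
# everything here is computed from first principles with base R.

# emission density of one observation (step, angle) in state k; missing
# components contribute a factor of 1
oracle_dens <- function(step, angle, em, k) {
  d <- 1
  if (!is.na(step)) {
    shape <- (em$step_mean[k] / em$step_sd[k])^2
    scale <- em$step_sd[k]^2 / em$step_mean[k]
    d <- d * dgamma(step, shape, scale = scale)
  }
  if (!is.na(angle)) {
    d <- d * movestates::dvonmises(angle, em$angle_mean[k], em$angle_conc[k])
  }
  d
}

# per-step transition matrices Gamma(z_t) and the initial distribution
# (stationary at the first covariate row), computed with base R only
oracle_gammas <- function(spec, Z) {
  n <- spec$n_states
  lapply(seq_len(nrow(Z)), function(t) {
    if (n == 1) return(matrix(1, 1, 1))
    eta <- as.numeric(Z[t, ] %*% spec$beta)
    g <- matrix(0, n, n)
    cc <- 1
    for (i in seq_len(n)) {
      e <- rep(0, n)
      for (j in seq_len(n)) {
        if (i == j) next
        e[j] <- eta[cc]; cc <- cc + 1
      }
      g[i, ] <- exp(e) / sum(exp(e))
    }
    g
  })
}

oracle_initial <- function(gamma1) {
  n <- nrow(gamma1)
  if (n == 1) return(1)
  as.numeric(solve(t(diag(n) - gamma1 + 1), rep(1, n)))
}

# joint probability of one state sequence and the observations
oracle_joint <- function(states, step, angle, spec, gammas, delta) {
  em <- spec$emissions
  p <- delta[states[1]] * oracle_dens(step[1], angle[1], em, states[1])
  for (t in seq_along(states)[-1]) {
    p <- p * gammas[[t]][states[t - 1], states[t]] *
      oracle_dens(step[t], angle[t], em, states[t])
  }
  p
}

# all N^T sequences as rows
oracle_sequences <- function(n, T) {
  as.matrix(expand.grid(rep(list(seq_len(n)), T)))
}

# enumeration log-likelihood, Viterbi path (lowest-index tie break via
# ordered enumeration) and smoothed marginals for a single individual
oracle_enumerate <- function(spec, step, angle, Z) {
  T <- length(step)
  n <- spec$n_states
  gammas <- oracle_gammas(spec, Z)
  delta <- oracle_initial(gammas[[1]])
  seqs <- oracle_sequences(n, T)
  probs <- apply(seqs, 1, oracle_joint, step = step, angle = angle,
                 spec = spec, gammas = gammas, delta = delta)
  marg <- matrix(0, T, n)
  for (t in seq_len(T))
    for (k in seq_len(n))
      marg[t, k] <- sum(probs[seqs[, t] == k])
  marg <- marg / rowSums(marg)
  # expand.grid varies the first column fastest; for the lowest-index tie
  # break, order rows lexicographically and take the first argmax
  ord <- do.call(order, as.data.frame(seqs))
  probs_o <- probs[ord]
  seqs_o <- seqs[ord, , drop = FALSE]
  best <- which.max(probs_o)  # which.max returns the first maximum
  list(loglik = log(sum(probs)),
       viterbi = as.integer(seqs_o[best, ]),
       marginals = marg)
}

# a small 2-state toy spec with an optional covariate
toy_spec_2 <- function(covariates = character()) {
  p <- 1 + length(covariates)
  beta <- matrix(0, p, 2)
  beta[1, ] <- c(-1.2, -0.7)
  if (p > 1) beta[2, ] <- c(0.5, -0.4)
  movestates::hmm_spec(step_mean = c(0.3, 1.6), step_sd = c(0.15, 0.9),
                       angle_mean = c(0.2, -0.1), angle_conc = c(0.7, 3),
                       beta = beta, covariates = covariates)
}

toy_spec_3 <- function() {
  movestates::hmm_spec(step_mean = c(0.3, 1.2, 3.1), step_sd = c(0.12, 0.5, 1.0),
                       angle_mean = c(0, 0.3, -0.2), angle_conc = c(0.6, 1.5, 4),
                       diag_prob = 0.75)
}

# deterministic toy observation series with missing values
toy_obs <- function(T, seed = 42, miss_step = integer(), miss_angle = 1) {
  set.seed(seed)
  step <- round(rgamma(T, 2, scale = 0.5) + 0.05, 3)
  angle <- round(runif(T, -pi + 0.01, pi), 3)
  step[miss_step] <- NA
  angle[miss_angle] <- NA
  list(step = step, angle = angle)
}

# wrap raw vectors into a minimal step tibble the package accepts
as_step_tbl <- function(step, angle, id = "a", z = NULL, zname = "z") {
  tb <- tibble::tibble(
    id = id,
    t = as.POSIXct("2020-01-01", tz = "UTC") + seq_along(step) * 4800,
    x_km = 0, y_km = 0,
    step_km = step, angle_rad = angle
  )
  if (!is.null(z)) tb[[zname]] <- z
  tb
}

# a quick well-separated 3-state scenario for recovery-style tests
sim_toy_steps <- function(spec, n_tracks, n_steps, seed, landscape = NULL) {
  if (is.null(landscape))
    landscape <- movestates::make_landscape(99, 400, 400)
  tr <- movestates::simulate_tracks(spec, landscape, n_tracks = n_tracks,
                                    n_steps = n_steps, seed = seed)
  steps_and_angles(dplyr::rename(tr, timestamp = time))
}
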