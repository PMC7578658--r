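#' Stationary state probabilities over a covariate grid, with CIs
#'
#' For each covariate row `z` of the grid, the stationary distribution
#' `delta(z)` of the transition matrix `Gamma(z)` is the long-run state
#' occupancy at those covariate values. Confidence intervals come from the
#' delta method: the gradient of each `delta_k(z)` with respect to the
#' working-scale parameters is computed by central finite differences, the
#' parameter covariance is the inverse of the observed Hessian of the
#' negative log-likelihood, and the normal interval is clamped to
#' `[0, 1]`.
#'
#' @param fit a converged [fit_hmm()] object (with a positive-definite
#'   Hessian).
#' @param covariate_grid data frame with one column per fitted covariate
#'   (in any order; all fitted covariates must be present). For an
#'   intercept-only model, a zero-column data frame with `n` rows (or
#'   `NULL` for a single row).
#' @param level confidence level (default 0.95).
#' @return a tibble of class `ms_stationary` in long format: the grid
#'   columns, `state`, `delta`, `lower`, `upper`.
#' @export
stationary_curve <- function(fit, covariate_grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "move_hmm"))
  n <- fit$spec$n_states
  covs <- fit$covariates
  if (is.null(covariate_grid)) {
    covariate_grid <- tibble::tibble(.rows = 1)
  }
  covariate_grid <- tibble::as_tibble(covariate_grid)
  miss <- setdiff(covs, names(covariate_grid))
  if (length(miss) > 0)
    abort(paste0("covariate grid lacks column(s): ", paste(miss, collapse = ", ")))

  covmat <- covariance_matrix(fit)
  p <- 1L + length(covs)
  nb <- n * (n - 1)
  beta_idx <- 4L * n + seq_len(p * nb)
  sig_beta <- covmat[beta_idx, beta_idx, drop = FALSE]
  par0 <- fit$working_par
  zcrit <- qnorm(1 - (1 - level) / 2)

  delta_of <- function(beta_vec, z) {
    sp <- fit$spec
    sp$beta <- matrix(beta_vec, nrow = p, ncol = nb)
    stationary_dist(transition_matrix(sp, z))
  }

  rows <- purrr::map(seq_len(nrow(covariate_grid)), function(r) {
    z <- vapply(covs, function(cv) covariate_grid[[cv]][r], numeric(1))
    b0 <- par0[beta_idx]
    delta <- delta_of(b0, z)
    grad <- matrix(0, length(b0), n)
    for (q in seq_along(b0)) {
      h <- 1e-6 * (abs(b0[q]) + 1e-6)
      bp <- b0; bp[q] <- bp[q] + h
      bm <- b0; bm[q] <- bm[q] - h
      grad[q, ] <- (delta_of(bp, z) - delta_of(bm, z)) / (2 * h)
    }
    se <- sqrt(pmax(0, colSums(grad * (sig_beta %*% grad))))
    dplyr::bind_cols(
      covariate_grid[rep(r, n), , drop = FALSE],
      tibble::tibble(
        state = seq_len(n),
        delta = delta,
        lower = pmax(0, delta - zcrit * se),
        upper = pmin(1, delta + zcrit * se)
      )
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ms_stationary", class(out))
  attr(out, "level") <- level
  out
}

# Inverse of the observed Hessian of the negative log-likelihood.
covariance_matrix <- function(fit) {
  if (is.null(fit$hessian)) abort("fit carries no Hessian.")
  ch <- tryCatch(chol(fit$hessian), error = function(e) NULL)
  if (is.null(ch))
    abort(paste0("the Hessian is not positive definite, so delta-method ",
                 "intervals are unavailable; refit with more data or more ",
                 "starts."))
  chol2inv(ch)
}
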