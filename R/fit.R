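# ---- internal data marshalling -------------------------------------------

# Flatten a step tibble into the arrays the C++ recursions consume.
# Rows are grouped by individual (order of first appearance, stable);
# missing covariate rows (missing positions) are filled by last observation
# carried forward within each individual, then backward for leading gaps:
# transitions must still advance across missing slots, and the footprint at
# an unobserved fix is best approximated by the nearest known one.
build_hmm_data <- function(steps, covariates) {
  miss <- setdiff(covariates, names(steps))
  if (length(miss) > 0)
    abort(paste0("step table lacks covariate column(s): ",
                 paste(miss, collapse = ", ")))
  ord <- order(match(steps$id, unique(steps$id)))
  steps <- steps[ord, ]
  bounds <- c(0L, cumsum(rle(as.character(steps$id))$lengths))
  p <- 1L + length(covariates)
  Z <- matrix(1, nrow(steps), p)
  if (length(covariates) > 0) {
    Z[, -1] <- as.matrix(steps[covariates])
    for (tr in seq_len(length(bounds) - 1)) {
      rows <- (bounds[tr] + 1):bounds[tr + 1]
      for (q in 2:p) {
        v <- Z[rows, q]
        if (anyNA(v)) {
          idx <- seq_along(v)
          known <- which(!is.na(v))
          if (length(known) == 0)
            abort("an individual has no known covariate values.")
          filled <- known[pmax(1, findInterval(idx, known))]
          Z[rows, q] <- v[filled]
        }
      }
    }
  }
  step <- as.numeric(steps$step_km)
  angle <- as.numeric(steps$angle_rad)
  sobs <- !is.na(step)
  aobs <- !is.na(angle)
  # sufficient statistics of both emission families, so each likelihood
  # evaluation needs no log/cos calls per observation
  lstep <- ifelse(sobs, log(pmax(step, 1e-300)), 0)
  step0 <- ifelse(sobs, step, 0)
  cosang <- ifelse(aobs, cos(angle), 0)
  sinang <- ifelse(aobs, sin(angle), 0)
  list(step = step, angle = angle, step0 = step0, lstep = lstep,
       cosang = cosang, sinang = sinang, sobs = sobs, aobs = aobs,
       Z = Z, bounds = as.integer(bounds), steps = steps)
}

pack_par <- function(spec) {
  em <- spec$emissions
  c(log(em$step_mean), log(em$step_sd), em$angle_mean, log(em$angle_conc),
    as.vector(spec$beta))
}

unpack_par <- function(par, n, p) {
  mu <- exp(par[seq_len(n)])
  sigma <- exp(par[n + seq_len(n)])
  amean <- wrap_angle(par[2 * n + seq_len(n)])
  kappa <- exp(par[3 * n + seq_len(n)])
  nb <- n * (n - 1)
  beta <- matrix(par[4 * n + seq_len(p * nb)], nrow = p, ncol = nb)
  list(mu = mu, sigma = sigma, amean = amean, kappa = kappa, beta = beta)
}

n_hmm_params <- function(n, n_cov) 4L * n + (1L + n_cov) * n * (n - 1L)

# ---- likelihood -----------------------------------------------------------

#' Forward log-likelihood of a movement HMM
#'
#' Scaled forward recursion, summed over individuals. A missing step or
#' angle contributes an emission factor of 1 for the missing component;
#' transitions still advance across missing slots. The initial distribution
#' of each individual is the stationary distribution of the transition
#' matrix at that individual's first covariate row.
#'
#' @param spec an [hmm_spec()].
#' @param steps a step tibble (see [prepare_steps()]) containing `id`,
#'   `step_km`, `angle_rad` and the spec's covariate columns.
#' @return the log-likelihood (a single number).
#' @export
forward_loglik <- function(spec, steps) {
  stopifnot(inherits(spec, "ms_hmm_spec"))
  d <- build_hmm_data(steps, spec$covariates)
  em <- spec$emissions
  nll <- ms_nll(d$step0, d$lstep, d$cosang, d$sinang, d$sobs, d$aobs,
                d$Z, spec$beta, em$step_mean, em$step_sd,
                em$angle_mean, em$angle_conc, d$bounds)
  if (nll >= 1e10) abort("invalid specification: likelihood not computable.")
  -nll
}

# ---- multi-start fitting --------------------------------------------------

make_starts <- function(d, n, p_cov, n_starts) {
  obs <- d$step[!is.na(d$step)]
  qs <- quantile(obs, probs = seq(0, 1, length.out = n + 1), names = FALSE)
  grp <- cut(obs, breaks = unique(c(-Inf, qs[-c(1, n + 1)], Inf)),
             labels = FALSE)
  mu0 <- as.numeric(tapply(obs, grp, mean))
  sd0 <- as.numeric(tapply(obs, grp, sd))
  if (length(mu0) < n) mu0 <- quantile(obs, (seq_len(n) - 0.5) / n, names = FALSE)
  sd0[is.na(sd0) | sd0 <= 0] <- mu0[is.na(sd0) | sd0 <= 0] / 2
  sd0 <- pmax(sd0, 1e-4)
  nb <- n * (n - 1)
  icpt <- if (n > 1) log((0.2 / (n - 1)) / 0.8) else numeric(0)
  lapply(seq_len(n_starts), function(i) {
    jit <- i > 1
    mu <- mu0 * if (jit) exp(rnorm(n, 0, 0.2)) else 1
    sg <- sd0 * if (jit) exp(rnorm(n, 0, 0.2)) else 1
    am <- if (jit) rnorm(n, 0, 0.3) else rep(0, n)
    kp <- if (jit) exp(rnorm(n, 0, 0.3)) else rep(1, n)
    beta <- matrix(0, 1 + p_cov, nb)
    if (n > 1) {
      beta[1, ] <- icpt + if (jit) rnorm(nb, 0, 0.3) else 0
      if (p_cov > 0 && jit) beta[-1, ] <- rnorm(p_cov * nb, 0, 0.1)
    }
    c(log(mu), log(sg), am, log(kp), as.vector(beta))
  })
}

# Permute states so step means increase, remapping emissions, transition
# coefficients, the working parameter vector and the Hessian consistently.
relabel_by_mean <- function(est, par, hessian, n, p) {
  ordr <- order(est$mu)
  if (all(ordr == seq_len(n))) return(list(est = est, par = par, hessian = hessian))
  nb <- n * (n - 1)
  # column index of ordered off-diagonal pair (i, j)
  colof <- matrix(0L, n, n)
  cc <- 1L
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    colof[i, j] <- cc; cc <- cc + 1L
  }
  colmap <- integer(nb)                               # new col -> old col
  for (a in seq_len(n)) for (b in seq_len(n)) if (a != b)
    colmap[colof[a, b]] <- colof[ordr[a], ordr[b]]
  perm <- c(ordr, n + ordr, 2 * n + ordr, 3 * n + ordr,
            4 * n + as.vector(outer(seq_len(p), (colmap - 1) * p, `+`)))
  list(
    est = list(mu = est$mu[ordr], sigma = est$sigma[ordr],
               amean = est$amean[ordr], kappa = est$kappa[ordr],
               beta = est$beta[, colmap, drop = FALSE]),
    par = par[perm],
    hessian = if (is.null(hessian)) NULL else hessian[perm, perm, drop = FALSE]
  )
}

#' Fit a movement HMM by maximum likelihood
#'
#' Maximises the forward log-likelihood over an unconstrained working
#' scale (log step mean/SD and concentration, free angle mean, free
#' transition coefficients) by BFGS. Robustness to local maxima comes from
#' multiple jittered initial values: every start is explored with a capped
#' number of iterations and the best one is polished to full convergence,
#' where the Hessian of the negative log-likelihood is also evaluated.
#' States are relabelled so step means increase.
#'
#' @inheritParams forward_loglik
#' @param n_states number of latent states.
#' @param covariates character vector of transition covariate column names
#'   (use `character(0)` for an intercept-only transition model).
#' @param n_starts number of initial values (the first is unjittered).
#' @param seed seed for start jitter.
#' @param tol relative convergence tolerance of the final optimisation.
#' @param explore_maxit BFGS iteration cap per exploratory start.
#' @param maxit iteration cap for the final polish.
#' @param hessian evaluate the Hessian at the optimum? Required for
#'   delta-method intervals ([stationary_curve()]); skipping it saves time
#'   when only point estimates, decoding or AIC are needed.
#' @return an object of class `move_hmm` with elements `spec` (estimated
#'   [hmm_spec()]), `loglik`, `n_params`, `aic`, `working_par`, `hessian`,
#'   `convergence`, `n_starts`, `starts` (per-start diagnostics) and
#'   `n_obs`.
#' @export
fit_hmm <- function(steps, n_states, covariates = character(), n_starts = 10,
                    seed = 1, tol = 1e-9, explore_maxit = 30, maxit = 1000,
                    hessian = TRUE) {
  if (n_states < 1) abort("`n_states` must be at least 1.")
  if (n_starts < 1) abort("`n_starts` must be at least 1.")
  d <- build_hmm_data(steps, covariates)
  obs_per_id <- tapply(!is.na(d$step), d$steps$id, sum)
  if (any(obs_per_id == 0))
    abort("every individual needs at least one observed step.")
  n <- as.integer(n_states)
  p_cov <- length(covariates)

  # the C++ pass returns value and analytic gradient together; cache the
  # last evaluation since optim() asks for both at the same point
  cache <- new.env(parent = emptyenv())
  eval_point <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    u <- unpack_par(par, n, 1L + p_cov)
    res <- ms_nll_grad(d$step0, d$lstep, d$cosang, d$sinang, d$sobs, d$aobs,
                       d$Z, u$beta, u$mu, u$sigma, u$amean, u$kappa, d$bounds)
    cache$par <- par
    cache$res <- res
    res
  }
  fn <- function(par) eval_point(par)$nll
  gr <- function(par) eval_point(par)$grad

  local_rng(seed)
  starts <- make_starts(d, n, p_cov, n_starts)
  explore <- purrr::map(starts, function(s) {
    tryCatch(
      optim(s, fn, gr, method = "BFGS",
            control = list(maxit = explore_maxit, reltol = 1e-8)),
      error = function(e) list(par = s, value = Inf, convergence = 99L,
                               message = conditionMessage(e))
    )
  })
  values <- purrr::map_dbl(explore, "value")
  diag_tbl <- tibble::tibble(
    start = seq_len(n_starts),
    nll_explore = values,
    convergence = purrr::map_int(explore, ~ as.integer(.x$convergence))
  )
  if (all(!is.finite(values))) {
    abort(paste0("no start converged; per-start diagnostics:\n",
                 paste(utils::capture.output(print(diag_tbl)), collapse = "\n")))
  }
  best <- which.min(values)
  polish <- optim(explore[[best]]$par, fn, gr, method = "BFGS",
                  control = list(maxit = maxit, reltol = tol),
                  hessian = hessian)
  if (!hessian) polish$hessian <- NULL

  est <- unpack_par(polish$par, n, 1L + p_cov)
  rl <- relabel_by_mean(est, polish$par, polish$hessian, n, 1L + p_cov)
  est <- rl$est
  spec <- hmm_spec(est$mu, est$sigma, est$amean, est$kappa,
                   beta = est$beta, covariates = covariates)
  ll <- -polish$value
  p_all <- n_hmm_params(n, p_cov)
  structure(
    list(
      spec = spec,
      loglik = ll,
      n_params = p_all,
      aic = -2 * ll + 2 * p_all,
      working_par = rl$par,
      hessian = rl$hessian,
      convergence = polish$convergence,
      n_starts = n_starts,
      starts = diag_tbl,
      best_start = best,
      seed = seed,
      covariates = covariates,
      n_obs = sum(!is.na(d$step)) + sum(!is.na(d$angle)),
      n_records = length(d$step),
      n_individuals = length(d$bounds) - 1L
    ),
    class = "move_hmm"
  )
}

#' @export
print.move_hmm <- function(x, ...) {
  cat(sprintf(
    "Movement HMM fit: %d states, %d individuals, %d records\n",
    x$spec$n_states, x$n_individuals, x$n_records))
  cat(sprintf("log-likelihood %.3f, %d parameters, AIC %.1f (convergence %d)\n",
              x$loglik, x$n_params, x$aic, x$convergence))
  print(x$spec)
  invisible(x)
}

#' @export
tidy.move_hmm <- function(x, ...) {
  em <- x$spec$emissions |>
    tidyr::pivot_longer(-"state", names_to = "term", values_to = "estimate") |>
    dplyr::mutate(component = "emission", .before = 1)
  if (x$spec$n_states == 1) return(em)
  tb <- as.data.frame(x$spec$beta)
  tb$term <- rownames(x$spec$beta)
  tr <- tb |>
    tidyr::pivot_longer(-"term", names_to = "transition",
                        values_to = "estimate") |>
    dplyr::mutate(component = "transition",
                  state = as.integer(sub("->.*", "", .data$transition)),
                  .before = 1)
  dplyr::bind_rows(em, tr)
}

#' @export
glance.move_hmm <- function(x, ...) {
  tibble::tibble(
    n_states = x$spec$n_states,
    logLik = x$loglik,
    n_params = x$n_params,
    AIC = x$aic,
    n_obs = x$n_obs,
    n_individuals = x$n_individuals,
    convergence = x$convergence,
    n_starts = x$n_starts
  )
}

#' Compare movement HMMs with different numbers of states
#'
#' Fits one model per entry of `state_counts` and tabulates
#' log-likelihood, parameter count, AIC and the AIC difference to the best
#' model.
#'
#' @inheritParams fit_hmm
#' @param state_counts integer vector of state numbers to compare.
#' @return a list of class `ms_model_select`: `table` (tibble with
#'   `n_states`, `loglik`, `n_params`, `aic`, `delta_aic`), `best_n`, and
#'   `fits` (named list of `move_hmm` objects).
#' @export
model_select <- function(steps, state_counts = c(2, 3), covariates = character(),
                         n_starts = 10, seed = 1, ...) {
  if (length(state_counts) == 0) abort("`state_counts` must be non-empty.")
  fits <- purrr::map(state_counts, function(nn) {
    tryCatch(
      fit_hmm(steps, n_states = nn, covariates = covariates,
              n_starts = n_starts, seed = seed + nn, ...),
      error = function(e)
        abort(sprintf("fitting the %d-state model failed: %s",
                      nn, conditionMessage(e)))
    )
  })
  names(fits) <- paste0("N", state_counts)
  tab <- tibble::tibble(
    n_states = as.integer(state_counts),
    loglik = purrr::map_dbl(fits, "loglik"),
    n_params = purrr::map_int(fits, ~ as.integer(.x$n_params)),
    aic = purrr::map_dbl(fits, "aic")
  ) |>
    dplyr::mutate(delta_aic = .data$aic - min(.data$aic))
  structure(
    list(table = tab, best_n = tab$n_states[which.min(tab$aic)], fits = fits),
    class = "ms_model_select"
  )
}

#' @export
print.ms_model_select <- function(x, ...) {
  cat("Movement HMM model selection (AIC):\n")
  print(x$table)
  cat(sprintf("Best supported number of states: %d\n", x$best_n))
  invisible(x)
}
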