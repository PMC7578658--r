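# Run the full C++ decoding pass for a fit on a step table.
decode_pass <- function(fit, steps) {
  stopifnot(inherits(fit, "move_hmm"))
  d <- build_hmm_data(steps, fit$covariates)
  em <- fit$spec$emissions
  res <- ms_decode(d$step0, d$lstep, d$cosang, d$sinang, d$sobs, d$aobs,
                   d$Z, fit$spec$beta, em$step_mean, em$step_sd,
                   em$angle_mean, em$angle_conc, d$bounds)
  list(d = d, res = res)
}

#' Viterbi-decoded state sequence
#'
#' The jointly most probable state sequence per individual under the
#' fitted model; ties are broken toward the lower state index.
#'
#' @param fit a [fit_hmm()] object.
#' @param steps the step tibble the model was fitted to (or a compatible
#'   one).
#' @return the step tibble with a `viterbi_state` column.
#' @export
viterbi_states <- function(fit, steps) {
  pass <- decode_pass(fit, steps)
  out <- pass$d$steps
  out$viterbi_state <- as.integer(pass$res$viterbi)
  out
}

#' Forward-backward state probabilities
#'
#' Smoothed marginal probabilities of each state at each step, plus the
#' probability of the Viterbi-assigned state. The mean and SD of the
#' assigned-state probability (a standard summary of decoding confidence)
#' are attached as the `"assigned_summary"` attribute and available via
#' [assigned_state_summary()].
#'
#' @inheritParams viterbi_states
#' @return the step tibble with `viterbi_state`, one `prob_<k>` column per
#'   state, and `prob_assigned`.
#' @export
state_probs <- function(fit, steps) {
  pass <- decode_pass(fit, steps)
  out <- pass$d$steps
  post <- pass$res$posterior
  n <- fit$spec$n_states
  vit <- as.integer(pass$res$viterbi)
  out$viterbi_state <- vit
  for (k in seq_len(n)) out[[paste0("prob_", k)]] <- post[, k]
  out$prob_assigned <- post[cbind(seq_len(nrow(post)), vit)]
  attr(out, "assigned_summary") <- tibble::tibble(
    mean_prob = mean(out$prob_assigned),
    sd_prob = sd(out$prob_assigned)
  )
  out
}

#' @rdname state_probs
#' @param decoded output of [state_probs()].
#' @export
assigned_state_summary <- function(decoded) {
  attr(decoded, "assigned_summary")
}

#' One-step-ahead pseudo-residuals
#'
#' For each observed component, the forecast CDF under the fitted model (a
#' forward-weighted mixture of the state-dependent CDFs, using all data up
#' to the previous step) is mapped through the standard-normal quantile
#' function. Under a correctly specified model these residuals are
#' standard normal. The angle CDF is taken on `(-pi, pi]` anchored at
#' `-pi`. Missing observations give missing residuals.
#'
#' @inheritParams viterbi_states
#' @return the step tibble with `step_resid` and `angle_resid` columns.
#' @export
pseudo_residuals <- function(fit, steps) {
  pass <- decode_pass(fit, steps)
  out <- pass$d$steps
  w <- pass$res$weights
  em <- fit$spec$emissions
  n <- fit$spec$n_states
  shape <- (em$step_mean / em$step_sd)^2
  scale <- em$step_sd^2 / em$step_mean

  u_step <- rep(NA_real_, nrow(out))
  obs_s <- !is.na(out$step_km)
  if (any(obs_s)) {
    acc <- 0
    for (k in seq_len(n))
      acc <- acc + w[obs_s, k] * pgamma(out$step_km[obs_s], shape[k],
                                        scale = scale[k])
    u_step[obs_s] <- acc
  }
  u_ang <- rep(NA_real_, nrow(out))
  obs_a <- !is.na(out$angle_rad)
  if (any(obs_a)) {
    acc <- 0
    for (k in seq_len(n))
      acc <- acc + w[obs_a, k] * pvonmises(out$angle_rad[obs_a],
                                           em$angle_mean[k], em$angle_conc[k])
    u_ang[obs_a] <- acc
  }
  eps <- 1e-12
  out$step_resid <- qnorm(pmin(pmax(u_step, eps), 1 - eps))
  out$angle_resid <- qnorm(pmin(pmax(u_ang, eps), 1 - eps))
  out
}
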