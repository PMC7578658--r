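#' Observed step/angle distributions with fitted state densities
#'
#' Histograms of the observed step lengths and turning angles overlaid
#' with the fitted state-dependent densities, each weighted by that
#' state's mean smoothed occupancy probability.
#'
#' @param fit a [fit_hmm()] object.
#' @param steps the step tibble used for fitting.
#' @param n_grid resolution of the density curves.
#' @return a ggplot object (facets: component).
#' @export
plot_state_distributions <- function(fit, steps, n_grid = 300) {
  sp <- state_probs(fit, steps)
  n <- fit$spec$n_states
  em <- fit$spec$emissions
  wts <- vapply(seq_len(n), function(k) mean(sp[[paste0("prob_", k)]]),
                numeric(1))
  obs <- dplyr::bind_rows(
    tibble::tibble(component = "step length (km)",
                   value = sp$step_km[!is.na(sp$step_km)]),
    tibble::tibble(component = "turning angle (rad)",
                   value = sp$angle_rad[!is.na(sp$angle_rad)])
  )
  smax <- max(sp$step_km, na.rm = TRUE)
  sgrid <- seq(1e-4, smax, length.out = n_grid)
  agrid <- seq(-pi, pi, length.out = n_grid)
  dens <- dplyr::bind_rows(purrr::map(seq_len(n), function(k) {
    shape <- (em$step_mean[k] / em$step_sd[k])^2
    scale <- em$step_sd[k]^2 / em$step_mean[k]
    dplyr::bind_rows(
      tibble::tibble(component = "step length (km)", state = factor(k),
                     value = sgrid,
                     density = wts[k] * dgamma(sgrid, shape, scale = scale)),
      tibble::tibble(component = "turning angle (rad)", state = factor(k),
                     value = agrid,
                     density = wts[k] * dvonmises(agrid, em$angle_mean[k],
                                                  em$angle_conc[k]))
    )
  }))
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = obs,
      ggplot2::aes(x = .data$value, y = ggplot2::after_stat(density)),
      bins = 40, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$value, y = .data$density,
                   colour = .data$state), linewidth = 0.8) +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::labs(x = NULL, y = "density", colour = "state") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_stationary <- function(object, covariate = NULL, ...) {
  covs <- setdiff(names(object), c("state", "delta", "lower", "upper"))
  if (is.null(covariate)) {
    covariate <- covs[which.max(vapply(covs, function(cv)
      length(unique(object[[cv]])), numeric(1)))]
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[covariate]], y = .data$delta,
                               colour = factor(.data$state),
                               fill = factor(.data$state))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = covariate, y = "stationary state probability",
                  colour = "state", fill = "state") +
    ggplot2::theme_minimal()
}

#' Map of decoded movement states
#'
#' Paths and points coloured by the Viterbi state, one panel per
#' individual.
#'
#' @param decoded output of [viterbi_states()] or [state_probs()].
#' @return a ggplot object.
#' @export
plot_decoded_map <- function(decoded) {
  ggplot2::ggplot(decoded,
                  ggplot2::aes(x = .data$x_km, y = .data$y_km)) +
    ggplot2::geom_path(colour = "grey70", linewidth = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$viterbi_state)),
                        size = 0.5, na.rm = TRUE) +
    ggplot2::facet_wrap(~id) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", colour = "state") +
    ggplot2::theme_minimal()
}

#' QQ plot of pseudo-residuals against the standard normal
#'
#' @param resids output of [pseudo_residuals()].
#' @return a ggplot object.
#' @export
plot_qq_residuals <- function(resids) {
  long <- resids |>
    dplyr::select("id", "t", "step_resid", "angle_resid") |>
    tidyr::pivot_longer(c("step_resid", "angle_resid"),
                        names_to = "component", values_to = "resid") |>
    dplyr::filter(!is.na(.data$resid))
  ggplot2::ggplot(long, ggplot2::aes(sample = .data$resid)) +
    ggplot2::stat_qq(size = 0.4, alpha = 0.4) +
    ggplot2::stat_qq_line(colour = "red") +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "standard normal quantiles", y = "pseudo-residual") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_trajectories <- function(object, ring_radius = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$id)) +
    ggplot2::geom_path(alpha = 0.25, linewidth = 0.2) +
    ggplot2::annotate("point", x = 0, y = 0, colour = "red", shape = 3,
                      size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
  if (!is.null(ring_radius)) {
    th <- seq(0, 2 * pi, length.out = 200)
    ring <- tibble::tibble(x = ring_radius * cos(th),
                           y = ring_radius * sin(th), id = NA)
    p <- p + ggplot2::geom_path(data = ring, colour = "steelblue",
                                linetype = 2)
  }
  p
}
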