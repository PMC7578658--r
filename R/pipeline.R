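# ---- configuration --------------------------------------------------------

#' Default pipeline configuration
#'
#' A plain list describing one end-to-end analysis: simulation settings,
#' preparation filters, model-selection settings and output paths. Can be
#' written to / read from YAML.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed recorded in every output.
#' @return a named list.
#' @export
default_config <- function(out_dir = "movestates-run", seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    landscape = list(n_cells_x = 80, n_cells_y = 80, value_range = c(2, 16),
                     park_fraction = 0.5, cell_size = 1),
    simulate = list(n_tracks = 9, n_steps = 600, step_minutes = 80,
                    rest_prob = 0.1),
    denning_window = c(160, 220),
    prep = list(step_minutes = 80, tolerance_minutes = 5, min_step_km = 0.2),
    fit = list(state_counts = c(2, 3), covariates = c("hfi_std", "in_park", "denning"),
               n_starts = 10),
    stationary = list(grid_points = 25),
    connectivity = list(n_individuals = 1000, n_steps = 100, ring_radius = 60)
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a configuration list.
#' @param path YAML file path.
#' @return `write_config()` the path invisibly; `read_config()` the list.
#' @export
write_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

validate_config <- function(config) {
  dw <- config$denning_window
  if (length(dw) != 2 || dw[1] > dw[2])
    abort("invalid denning window: start must not exceed end.")
  if (is.null(config$out_dir)) abort("config needs an `out_dir`.")
  if (is.null(config$seed)) abort("config needs a `seed`.")
  invisible(config)
}

run_log <- function(out_dir, lines) {
  path <- file.path(out_dir, "run.log")
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  cat(paste0(stamp, " ", lines, "\n"), file = path, append = TRUE, sep = "")
  invisible(path)
}

config_hash <- function(config) rlang::hash(config)

# ---- pipeline stages ------------------------------------------------------

#' Simulate a synthetic scenario to disk
#'
#' Builds the landscape and the movement tracks from the default
#' three-state generating model, injects resting steps, and writes
#' `fixes.csv`, the landscape ASCII grids and the configuration used.
#' Re-running with the same configuration reproduces the files
#' byte-identically.
#'
#' @param config a [default_config()]-style list.
#' @return invisibly, a list with the landscape, tracks, fixes and file
#'   paths.
#' @export
run_simulate <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  lc <- config$landscape
  landscape <- make_landscape(config$seed, lc$n_cells_x, lc$n_cells_y,
                              value_range = as.numeric(lc$value_range),
                              park_fraction = lc$park_fraction,
                              cell_size = lc$cell_size)
  spec <- default_movement_spec(step_minutes = config$simulate$step_minutes,
                                covariates = config$fit$covariates)
  tracks <- simulate_tracks(spec, landscape,
                            n_tracks = config$simulate$n_tracks,
                            n_steps = config$simulate$n_steps,
                            step_minutes = config$simulate$step_minutes,
                            denning_window = as.numeric(config$denning_window),
                            seed = config$seed + 1)
  fixes <- inject_resting(tracks, config$simulate$rest_prob,
                          seed = config$seed + 2)
  paths <- list(
    fixes = file.path(config$out_dir, "fixes.csv"),
    landscape = file.path(config$out_dir, "landscape"),
    config = file.path(config$out_dir, "config.yaml")
  )
  write_fixes(fixes, paths$fixes)
  write_landscape(landscape, paths$landscape)
  write_config(config, paths$config)
  run_log(config$out_dir, sprintf("simulate: seed=%d hash=%s fixes=%d",
                                  config$seed, config_hash(config),
                                  nrow(fixes)))
  invisible(list(landscape = landscape, spec = spec, tracks = tracks,
                 fixes = fixes, paths = paths))
}

#' Fit, decode and summarise a simulated or real scenario
#'
#' Reads the fixes and landscape written by [run_simulate()] (or supplied
#' by the user in the same formats), prepares steps, compares state
#' counts by AIC, decodes the best model, computes stationary-probability
#' curves for each covariate with 95% intervals, pseudo-residuals, and
#' writes all artifacts (JSON fit, CSV tables, PNG figures, run log).
#'
#' @param config a [default_config()]-style list whose `out_dir` contains
#'   `fixes.csv` and the landscape grids.
#' @return invisibly, a list with the prepared steps, the model-selection
#'   object, the best fit, decoded steps, stationary curves and residuals.
#' @export
run_fit <- function(config = default_config()) {
  validate_config(config)
  out <- config$out_dir
  fixes <- read_fixes(file.path(out, "fixes.csv"))
  landscape <- read_landscape(file.path(out, "landscape"))
  run_log(out, sprintf("fit: seed=%d hash=%s", config$seed,
                       config_hash(config)))

  prep <- prepare_steps(fixes, landscape,
                        step_minutes = config$prep$step_minutes,
                        tolerance_minutes = config$prep$tolerance_minutes,
                        min_km = config$prep$min_step_km,
                        denning_window = as.numeric(config$denning_window))
  steps <- prep$steps
  run_log(out, sprintf("prep: %d records, %d observed steps", nrow(steps),
                       sum(!is.na(steps$step_km))))

  covs <- config$fit$covariates
  keep <- vapply(covs, function(cv) {
    v <- steps[[cv]][!is.na(steps[[cv]])]
    length(unique(v)) > 1
  }, logical(1))
  if (any(!keep))
    run_log(out, sprintf("dropping constant covariate(s): %s",
                         paste(covs[!keep], collapse = ", ")))
  covs <- covs[keep]

  sel <- model_select(steps,
                      state_counts = as.integer(config$fit$state_counts),
                      covariates = covs,
                      n_starts = config$fit$n_starts,
                      seed = config$seed + 10)
  readr::write_csv(sel$table, file.path(out, "aic_table.csv"))
  fit <- sel$fits[[paste0("N", sel$best_n)]]
  run_log(out, sprintf("model selection: best N=%d (AIC %.1f)", sel$best_n,
                       min(sel$table$aic)))

  decoded <- state_probs(fit, steps)
  readr::write_csv(decoded, file.path(out, "decoded.csv"))
  summ <- assigned_state_summary(decoded)
  run_log(out, sprintf("decoding: mean assigned-state probability %.3f (SD %.3f)",
                       summ$mean_prob, summ$sd_prob))

  curves <- purrr::map(covs, function(cv) {
    grid <- stationary_grid(steps, fit$covariates, cv,
                            n = config$stationary$grid_points)
    stationary_curve(fit, grid)
  })
  names(curves) <- covs
  all_curves <- dplyr::bind_rows(curves, .id = "sweep")
  readr::write_csv(all_curves, file.path(out, "stationary.csv"))

  resids <- pseudo_residuals(fit, steps)
  readr::write_csv(
    dplyr::select(resids, "id", "t", "step_resid", "angle_resid"),
    file.path(out, "residuals.csv"))

  write_fit_json(fit, sel, config, file.path(out, "fit.json"))

  ggplot2::ggsave(file.path(out, "fig_state_distributions.png"),
                  plot_state_distributions(fit, steps),
                  width = 9, height = 4, dpi = 150)
  for (cv in covs)
    ggplot2::ggsave(file.path(out, paste0("fig_stationary_", cv, ".png")),
                    autoplot(curves[[cv]], covariate = cv),
                    width = 6, height = 4, dpi = 150)
  ggplot2::ggsave(file.path(out, "fig_decoded_map.png"),
                  plot_decoded_map(decoded), width = 9, height = 7, dpi = 150)
  ggplot2::ggsave(file.path(out, "fig_qq_residuals.png"),
                  plot_qq_residuals(resids), width = 8, height = 4, dpi = 150)
  run_log(out, "fit: artifacts written")
  invisible(list(steps = steps, stats = prep$stats, selection = sel,
                 fit = fit, decoded = decoded, stationary = all_curves,
                 residuals = resids))
}

# Sweep one covariate over the observed range while holding the others at
# zero (standardised footprint) or their modal value (indicators).
stationary_grid <- function(steps, covariates, sweep, n = 25) {
  v <- steps[[sweep]][!is.na(steps[[sweep]])]
  sweep_vals <- if (length(unique(v)) <= 2) sort(unique(v))
    else seq(min(v), max(v), length.out = n)
  grid <- tibble::tibble(.rows = length(sweep_vals))
  grid[[sweep]] <- sweep_vals
  for (cv in setdiff(covariates, sweep)) {
    w <- steps[[cv]][!is.na(steps[[cv]])]
    grid[[cv]] <- if (length(unique(w)) <= 2)
      as.numeric(names(sort(table(w), decreasing = TRUE))[1])
    else 0
  }
  grid[covariates]
}

write_fit_json <- function(fit, sel, config, path) {
  obj <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_states = fit$spec$n_states,
    loglik = fit$loglik,
    n_params = fit$n_params,
    aic = fit$aic,
    convergence = fit$convergence,
    n_starts = fit$n_starts,
    emissions = fit$spec$emissions,
    beta = list(rows = rownames(fit$spec$beta),
                cols = colnames(fit$spec$beta),
                values = unname(as.matrix(fit$spec$beta))),
    working_par = fit$working_par,
    hessian = fit$hessian,
    aic_table = sel$table
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' [run_simulate()], [run_fit()] and [run_connectivity()] in sequence
#' under one configuration.
#'
#' @param config a [default_config()]-style list.
#' @return invisibly, a list with the three stages' results.
#' @export
run_pipeline <- function(config = default_config()) {
  sim <- run_simulate(config)
  fit <- run_fit(config)
  conn <- run_connectivity(config)
  invisible(list(simulate = sim, fit = fit, connectivity = conn))
}

#' Run the connectivity demonstration
#'
#' Simulates the fast/shallow-turning pattern A and the slow/sharp-turning
#' pattern B, summarises ring connection for both, and writes the summary
#' CSV and a trajectory figure.
#'
#' @param config a [default_config()]-style list.
#' @return invisibly, a list with trajectories and summaries.
#' @export
run_connectivity <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cc <- config$connectivity
  pats <- default_patterns()
  trajs <- purrr::imap(pats, function(p, nm) {
    simulate_pattern(p, cc$n_individuals, cc$n_steps,
                     seed = config$seed + match(nm, names(pats)))
  })
  conns <- purrr::map(trajs, ring_connection, ring_radius = cc$ring_radius)
  summary <- dplyr::bind_rows(purrr::map(conns, "summary"))
  readr::write_csv(summary, file.path(config$out_dir, "connectivity.csv"))
  both <- dplyr::bind_rows(purrr::imap(trajs, function(tr, nm)
    dplyr::mutate(tibble::as_tibble(tr), pattern = nm)))
  th <- seq(0, 2 * pi, length.out = 200)
  ring <- tibble::tibble(x = cc$ring_radius * cos(th),
                         y = cc$ring_radius * sin(th), id = NA)
  fig <- ggplot2::ggplot(both, ggplot2::aes(x = .data$x, y = .data$y,
                                            group = .data$id)) +
    ggplot2::geom_path(alpha = 0.15, linewidth = 0.2) +
    ggplot2::geom_path(data = ring, colour = "steelblue", linetype = 2) +
    ggplot2::annotate("point", x = 0, y = 0, colour = "red", shape = 3,
                      size = 3) +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(config$out_dir, "fig_connectivity.png"), fig,
                  width = 10, height = 5, dpi = 150)
  run_log(config$out_dir,
          sprintf("connectivity: seed=%d hash=%s props=%s", config$seed,
                  config_hash(config),
                  paste(sprintf("%.3f", summary$prop_connected),
                        collapse = "/")))
  invisible(list(trajectories = trajs, connections = conns,
                 summary = summary))
}
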