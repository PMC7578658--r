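#' Snap fixes to a fixed time grid
#'
#' Hidden Markov models need constant time intervals between locations.
#' Each individual's fixes are snapped to a grid anchored at its first fix;
#' a grid slot is filled by the nearest fix within `tolerance_minutes`
#' (nearest fix wins when several compete), and slots with no such fix
#' become missing positions. No interpolation is performed.
#'
#' @param fixes tibble with `id`, `timestamp` (POSIXct), `x_km`, `y_km`,
#'   sorted in time within each individual; extra columns are carried
#'   through.
#' @param step_minutes grid spacing in minutes.
#' @param tolerance_minutes maximum |offset| for a fix to fill a slot.
#' @return a fix tibble on the grid, with `NA` positions for empty slots.
#' @export
regularize_fixes <- function(fixes, step_minutes = 80, tolerance_minutes = 5) {
  if (step_minutes <= 0) abort("`step_minutes` must be positive.")
  extra <- setdiff(names(fixes), c("id", "timestamp", "x_km", "y_km"))
  fixes |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      tt <- as.numeric(df$timestamp)
      if (anyDuplicated(tt))
        abort(sprintf("duplicate timestamps for individual '%s'.", key$id[1]))
      if (is.unsorted(tt)) df <- df[order(tt), ]
      tt <- as.numeric(df$timestamp)
      dt <- step_minutes * 60
      tol <- tolerance_minutes * 60
      k <- round((tt - tt[1]) / dt)
      off <- abs(tt - (tt[1] + k * dt))
      ok <- off <= tol
      n_slots <- max(k[ok]) + 1
      slot_of <- rep(NA_integer_, n_slots)
      cand <- which(ok)[order(off[ok])]      # nearest fix wins
      for (i in cand) {
        s <- k[i] + 1
        if (is.na(slot_of[s])) slot_of[s] <- i
      }
      out <- tibble::tibble(
        timestamp = df$timestamp[1] + (seq_len(n_slots) - 1) * dt,
        x_km = df$x_km[slot_of],
        y_km = df$y_km[slot_of]
      )
      for (cl in extra) out[[cl]] <- df[[cl]][slot_of]
      out
    }) |>
    dplyr::ungroup()
}

#' Compute step lengths and turning angles from regularised fixes
#'
#' One record per step: `step_km` is the Euclidean distance between
#' consecutive positions and `angle_rad` the signed change of heading
#' between consecutive displacement vectors (counterclockwise positive,
#' wrapped to `(-pi, pi]`). The angle is missing on each individual's first
#' step and wherever either adjacent displacement is missing or has zero
#' length. Covariate-relevant fields (`t`, `x_km`, `y_km` and any carried
#' columns such as `true_state`) refer to the step's start fix.
#'
#' @param fixes regularised fix tibble.
#' @return a step tibble: `id`, `t`, `x_km`, `y_km`, `step_km`,
#'   `angle_rad`, plus carried columns.
#' @export
steps_and_angles <- function(fixes) {
  extra <- setdiff(names(fixes), c("id", "timestamp", "x_km", "y_km"))
  fixes |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      m <- nrow(df)
      if (m < 2) {
        out <- tibble::tibble(t = df$timestamp[0], x_km = numeric(0),
                              y_km = numeric(0), step_km = numeric(0),
                              angle_rad = numeric(0))
        for (cl in extra) out[[cl]] <- df[[cl]][0]
        return(out)
      }
      dx <- diff(df$x_km)
      dy <- diff(df$y_km)
      len <- sqrt(dx^2 + dy^2)
      hd <- atan2(dy, dx)
      hd[is.na(len) | len == 0] <- NA_real_
      ang <- c(NA_real_, wrap_angle(diff(hd)))
      ang[is.na(c(NA_real_, head(hd, -1))) | is.na(hd)] <- NA_real_
      ang[1] <- NA_real_
      out <- tibble::tibble(
        t = df$timestamp[-m],
        x_km = df$x_km[-m],
        y_km = df$y_km[-m],
        step_km = len,
        angle_rad = ang
      )
      for (cl in extra) out[[cl]] <- df[[cl]][-m]
      out
    }) |>
    dplyr::ungroup()
}

#' Treat steps below a minimum length as missing
#'
#' Short steps are telemetry artefacts of resting animals; rather than
#' deleting the records (which would break the fixed time grid) their step
#' length and turning angle are set missing. Angles adjacent to a removed
#' displacement are also set missing, because the heading through it is
#' undefined. The number of records never changes.
#'
#' @param steps a step tibble from [steps_and_angles()].
#' @param min_km minimum step length in km (default 0.2).
#' @return the step tibble with short steps marked missing.
#' @export
filter_min_step <- function(steps, min_km = 0.2) {
  if (min_km < 0) abort("`min_km` must be non-negative.")
  steps |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(
      .drop_step = !is.na(.data$step_km) & .data$step_km < min_km,
      step_km = dplyr::if_else(.data$.drop_step, NA_real_, .data$step_km),
      angle_rad = dplyr::if_else(
        .drop_step | dplyr::lag(.data$.drop_step, default = FALSE),
        NA_real_, .data$angle_rad)
    ) |>
    dplyr::select(-".drop_step") |>
    dplyr::ungroup()
}

#' Attach landscape and seasonal covariates to steps
#'
#' Covariate values are taken at the step's start position: `hfi_raw` is
#' the footprint value of the cell containing it, `in_park` the
#' protected-area indicator, and `denning` is 1 when the step-start
#' timestamp's Julian day lies inside `denning_window` (inclusive on both
#' ends).
#'
#' @param steps a step tibble.
#' @param landscape an `ms_landscape`.
#' @param denning_window inclusive Julian-day pair.
#' @return the step tibble with `hfi_raw`, `in_park`, `denning` columns.
#' @export
extract_covariates <- function(steps, landscape, denning_window = c(160, 220)) {
  if (denning_window[1] > denning_window[2])
    abort("`denning_window` start must not exceed its end.")
  lk <- landscape_lookup(landscape, steps$x_km, steps$y_km)
  known <- !is.na(steps$x_km) & !is.na(steps$y_km)
  if (any(lk$outside & known)) {
    bad <- which(lk$outside & known)[1]
    abort(sprintf(
      "step-start position outside the landscape extent (individual '%s' at %s).",
      steps$id[bad], format(steps$t[bad])))
  }
  jd <- as.integer(lubridate::yday(steps$t))
  steps |>
    dplyr::mutate(
      hfi_raw = lk$hfi,
      in_park = lk$in_park,
      denning = as.integer(jd >= denning_window[1] & jd <= denning_window[2])
    )
}

#' Standardise the footprint covariate
#'
#' Centres and scales `hfi_raw` by its mean and population SD (divide by
#' `n`) over all records with a known value, adding an `hfi_std` column.
#' The stats are returned so prediction grids can be mapped onto the same
#' scale later.
#'
#' @param steps a step tibble with `hfi_raw`.
#' @param stats optional previously computed stats (a list/tibble with
#'   `mean` and `sd`) to apply instead of recomputing.
#' @return a list with `steps` (the tibble plus `hfi_std`) and `stats`
#'   (tibble with `mean`, `sd`).
#' @export
standardize_hfi <- function(steps, stats = NULL) {
  if (is.null(stats)) {
    v <- steps$hfi_raw[!is.na(steps$hfi_raw)]
    if (length(v) < 2) abort("need at least two records with a footprint value.")
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    if (s <= 0) abort("footprint covariate has zero variance.")
    stats <- tibble::tibble(mean = m, sd = s)
  }
  steps$hfi_std <- (steps$hfi_raw - stats$mean) / stats$sd
  list(steps = steps, stats = tibble::as_tibble(stats))
}

#' Human population pressure score
#'
#' Converts a human population density (people per square km) to the
#' pressure score used by footprint indices: the density is capped at
#' 1000 (the score saturates there) and scored as
#' `3.333 * log10(density + 1)`.
#'
#' @param density non-negative density, people per square km (vectorised).
#' @return numeric vector of pressure scores.
#' @export
#' @examples
#' pressure_score(c(0, 9, 1000, 5000))
pressure_score <- function(density) {
  if (any(!is.finite(density)) || any(density < 0))
    abort("`density` must be non-negative and finite.")
  3.333 * log10(pmin(density, 1000) + 1)
}

#' Full preparation pipeline from raw fixes to model-ready steps
#'
#' Chains [regularize_fixes()], [steps_and_angles()], [filter_min_step()],
#' [extract_covariates()] and [standardize_hfi()].
#'
#' @inheritParams regularize_fixes
#' @inheritParams filter_min_step
#' @inheritParams extract_covariates
#' @param stats optional standardisation stats to reuse.
#' @return a list with `steps` and `stats` as in [standardize_hfi()].
#' @export
prepare_steps <- function(fixes, landscape, step_minutes = 80,
                          tolerance_minutes = 5, min_km = 0.2,
                          denning_window = c(160, 220), stats = NULL) {
  fixes |>
    regularize_fixes(step_minutes, tolerance_minutes) |>
    steps_and_angles() |>
    filter_min_step(min_km) |>
    extract_covariates(landscape, denning_window) |>
    standardize_hfi(stats)
}
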