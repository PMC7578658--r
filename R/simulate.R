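#' Simulate multi-state movement tracks over a landscape
#'
#' Generates correlated-random-walk tracks governed by a movement HMM:
#' at the start of each step the covariates are read at the current
#' position (and timestamp, for the denning indicator), the next state is
#' drawn from the covariate-dependent transition row, a step length is
#' drawn from that state's gamma distribution and a turning angle from its
#' von Mises distribution; the heading accumulates turning angles (initial
#' heading uniform on `(-pi, pi]`) and the position advances by
#' `length * (cos(heading), sin(heading))`. Steps that would exit the grid
#' are reflected at the boundary (and the heading is mirrored so the walk's
#' angular dynamics are preserved); such steps are flagged since their
#' realised displacement no longer equals the drawn step length.
#'
#' The default track count and length mirror a field study of nine packs
#' with roughly 1700 regularised 80-minute steps each.
#'
#' @param spec an [hmm_spec()]; its `covariates` may contain `"hfi_std"`,
#'   `"in_park"` and `"denning"`.
#' @param landscape an [make_landscape()] landscape.
#' @param n_tracks,n_steps number of individuals and steps per individual.
#' @param step_minutes fixed step duration (minutes).
#' @param denning_window inclusive Julian-day window of the denning season.
#' @param seed integer seed; identical seeds give bit-identical tracks.
#' @param hfi_stats optional `c(mean, sd)` used to standardise the raw
#'   footprint for the `hfi_std` covariate during simulation; defaults to
#'   the mean and population SD of the landscape's cells.
#' @param start_time earliest possible track start (UTC); each track starts
#'   at a seeded uniform time within one year after it, so tracks sample
#'   both denning and non-denning seasons.
#' @return a tibble with one row per fix: `id`, `time`, `x_km`, `y_km`,
#'   `state` (state of the outgoing step; repeated on the final fix),
#'   `heading`, `step_km` and `angle_rad` (drawn values for the outgoing
#'   step, `NA` on the final fix) and `reflected`.
#' @export
simulate_tracks <- function(spec, landscape, n_tracks = 9, n_steps = 1688,
                            step_minutes = 80, denning_window = c(160, 220),
                            seed = 1, hfi_stats = NULL,
                            start_time = as.POSIXct("2017-01-01 00:00:00",
                                                    tz = "UTC")) {
  stopifnot(inherits(spec, "ms_hmm_spec"), inherits(landscape, "ms_landscape"))
  if (n_tracks < 1 || n_steps < 1) abort("need at least one track and one step.")
  unknown <- setdiff(spec$covariates, c("hfi_std", "in_park", "denning"))
  if (length(unknown) > 0)
    abort(paste0("covariates not provided by the landscape/clock: ",
                 paste(unknown, collapse = ", ")))
  if (is.null(hfi_stats)) {
    fp <- landscape$footprint
    hfi_stats <- c(mean = mean(fp), sd = sqrt(mean((fp - mean(fp))^2)))
  }
  local_rng(seed)

  n <- spec$n_states
  em <- spec$emissions
  ext <- landscape_extent(landscape)
  shape <- (em$step_mean / em$step_sd)^2
  scale <- em$step_sd^2 / em$step_mean
  cov_names <- spec$covariates
  need_hfi <- "hfi_std" %in% cov_names
  need_park <- "in_park" %in% cov_names
  need_den <- "denning" %in% cov_names

  out <- vector("list", n_tracks)
  for (tr in seq_len(n_tracks)) {
    # per-state pre-drawn emission pools (vectorised draws, indexed lazily)
    pool_step <- vapply(seq_len(n),
                        function(k) rgamma(n_steps, shape[k], scale = scale[k]),
                        numeric(n_steps))
    pool_step <- matrix(pool_step, nrow = n_steps)
    pool_angle <- vapply(seq_len(n),
                         function(k) rvonmises(n_steps, em$angle_mean[k],
                                               em$angle_conc[k]),
                         numeric(n_steps))
    pool_angle <- matrix(pool_angle, nrow = n_steps)

    t0 <- start_time + runif(1, 0, 365 * 86400)
    times <- t0 + (0:n_steps) * step_minutes * 60
    x <- numeric(n_steps + 1)
    y <- numeric(n_steps + 1)
    x[1] <- runif(1, ext["xmin"], ext["xmax"])
    y[1] <- runif(1, ext["ymin"], ext["ymax"])
    heading0 <- wrap_angle(runif(1, -pi, pi))

    state <- integer(n_steps)
    headings <- numeric(n_steps)
    steps <- numeric(n_steps)
    angles <- numeric(n_steps)
    refl <- logical(n_steps)

    zrow <- function(px, py, tt) {
      lk <- landscape_lookup(landscape, px, py)
      z <- numeric(0)
      if (need_hfi) z <- c(z, (lk$hfi - hfi_stats[[1]]) / hfi_stats[[2]])
      if (need_park) z <- c(z, lk$in_park)
      if (need_den) {
        jd <- as.integer(lubridate::yday(tt))
        z <- c(z, as.integer(jd >= denning_window[1] & jd <= denning_window[2]))
      }
      z
    }

    g <- transition_matrix(spec, zrow(x[1], y[1], times[1]))
    s <- sample.int(n, 1, prob = stationary_dist(g))
    h <- heading0
    for (t in seq_len(n_steps)) {
      if (t > 1) {
        g <- transition_matrix(spec, zrow(x[t], y[t], times[t]))
        s <- sample.int(n, 1, prob = g[s, ])
      }
      a <- pool_angle[t, s]
      l <- pool_step[t, s]
      h <- wrap_angle(h + a)
      nx <- x[t] + l * cos(h)
      ny <- y[t] + l * sin(h)
      hit <- FALSE
      while (nx < ext["xmin"] || nx > ext["xmax"]) {
        nx <- if (nx < ext["xmin"]) 2 * ext["xmin"] - nx else 2 * ext["xmax"] - nx
        h <- wrap_angle(pi - h)
        hit <- TRUE
      }
      while (ny < ext["ymin"] || ny > ext["ymax"]) {
        ny <- if (ny < ext["ymin"]) 2 * ext["ymin"] - ny else 2 * ext["ymax"] - ny
        h <- wrap_angle(-h)
        hit <- TRUE
      }
      x[t + 1] <- nx
      y[t + 1] <- ny
      state[t] <- s
      headings[t] <- h
      steps[t] <- l
      angles[t] <- a
      refl[t] <- hit
    }

    out[[tr]] <- tibble::tibble(
      id = sprintf("ind%02d", tr),
      time = times,
      x_km = x, y_km = y,
      state = c(state, state[n_steps]),
      heading = c(headings, headings[n_steps]),
      step_km = c(steps, NA_real_),
      angle_rad = c(angles, NA_real_),
      reflected = c(refl, NA)
    )
  }
  dplyr::bind_rows(out)
}

#' Convert simulated tracks to a raw fix table, injecting resting steps
#'
#' Emulates raw telemetry in which the animal sometimes rests through a fix
#' interval: a seeded random subset of steps is replaced by a near-zero
#' displacement (< 0.2 km), so the downstream minimum-step filter is
#' exercised. Subsequent fixes are left untouched, as in real data where a
#' resting interval changes where the next step starts.
#'
#' @param tracks output of [simulate_tracks()].
#' @param rest_prob probability that a step is replaced, in `[0, 1)`.
#' @param seed integer seed.
#' @return a CSV-ready fix tibble: `id`, `timestamp` (UTC), `x_km`, `y_km`,
#'   `true_state` (state of the step starting at that fix; `NA` on the
#'   final fix of each individual).
#' @export
inject_resting <- function(tracks, rest_prob = 0.1, seed = 1) {
  if (rest_prob < 0 || rest_prob >= 1) abort("`rest_prob` must be in [0, 1).")
  local_rng(seed)
  fixes <- tracks |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(
      true_state = dplyr::if_else(dplyr::row_number() == dplyr::n(),
                                  NA_integer_, as.integer(.data$state))
    ) |>
    dplyr::ungroup()
  if (rest_prob > 0) {
    grp <- fixes$id
    is_end <- c(FALSE, head(grp, -1) == tail(grp, -1))  # fix ends a step
    pick <- is_end & runif(nrow(fixes)) < rest_prob
    k <- sum(pick)
    if (k > 0) {
      # place the resting fix on the segment towards the original position
      # (both endpoints lie on the landscape, so the rest point does too)
      r <- runif(k, 0.02, 0.18)
      cur <- which(pick)
      prev <- cur - 1L
      dx <- fixes$x_km[cur] - fixes$x_km[prev]
      dy <- fixes$y_km[cur] - fixes$y_km[prev]
      dist <- sqrt(dx^2 + dy^2)
      fr <- ifelse(dist > 0, pmin(r, 0.9 * dist) / pmax(dist, 1e-12), 0)
      fixes$x_km[cur] <- fixes$x_km[prev] + fr * dx
      fixes$y_km[cur] <- fixes$y_km[prev] + fr * dy
    }
  }
  fixes |>
    dplyr::transmute(.data$id, timestamp = .data$time,
                     .data$x_km, .data$y_km, .data$true_state)
}

#' Write / read a fix table as CSV
#'
#' Timestamps are written as ISO-8601 UTC.
#'
#' @param fixes tibble with `id`, `timestamp`, `x_km`, `y_km` and optional
#'   extra columns.
#' @param path CSV file path.
#' @return `write_fixes()` returns `path` invisibly; `read_fixes()` the
#'   parsed tibble.
#' @export
write_fixes <- function(fixes, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(fixes, path)
  invisible(path)
}

#' @rdname write_fixes
#' @export
read_fixes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(timestamp = lubridate::as_datetime(.data$timestamp, tz = "UTC"))
}
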