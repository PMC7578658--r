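#' Define a movement pattern for the connectivity simulation
#'
#' A pattern couples a gamma speed (step length per time step) distribution
#' with a turning-angle distribution: either a single von Mises or a
#' two-component von Mises mixture (the second component, typically centred
#' at `pi`, models a higher probability of sharp turns).
#'
#' @param name pattern label.
#' @param speed_mean,speed_sd gamma mean and SD of the per-step distance
#'   (km).
#' @param angle_mean,angle_conc mean direction and concentration of the
#'   (first) turning-angle component.
#' @param mix_weight weight of the first component (1 = no mixture).
#' @param angle_mean2,angle_conc2 second mixture component.
#' @return an object of class `ms_pattern`.
#' @export
movement_pattern <- function(name, speed_mean, speed_sd,
                             angle_mean = 0, angle_conc = 1,
                             mix_weight = 1, angle_mean2 = pi,
                             angle_conc2 = 1) {
  if (speed_mean < 0 || speed_sd < 0) abort("speed parameters must be non-negative.")
  if (angle_conc < 0 || angle_conc2 < 0) abort("concentrations must be non-negative.")
  if (mix_weight < 0 || mix_weight > 1) abort("`mix_weight` must be in [0, 1].")
  structure(
    list(name = name, speed_mean = speed_mean, speed_sd = speed_sd,
         angle_mean = angle_mean, angle_conc = angle_conc,
         mix_weight = mix_weight, angle_mean2 = angle_mean2,
         angle_conc2 = angle_conc2),
    class = "ms_pattern"
  )
}

#' Default fast/slow movement patterns
#'
#' Pattern A moves fast with shallow turning angles; pattern B moves
#' slowly with a substantial probability of sharp turns (a mixture
#' component centred at `pi`). The parameter values are qualitative
#' emulations chosen to contrast connectivity outcomes.
#'
#' @return a named list of two [movement_pattern()] objects.
#' @export
default_patterns <- function() {
  list(
    A = movement_pattern("A", speed_mean = 1.0, speed_sd = 0.3,
                         angle_conc = 8),
    B = movement_pattern("B", speed_mean = 0.4, speed_sd = 0.2,
                         angle_conc = 2, mix_weight = 0.7,
                         angle_mean2 = pi, angle_conc2 = 2)
  )
}

#' Simulate correlated random walks for one movement pattern
#'
#' Every individual starts at the origin with a uniform initial heading;
#' at each of `n_steps` time steps a speed and a turning angle are drawn
#' independently and the position advances.
#'
#' @param pattern an [movement_pattern()].
#' @param n_individuals number of walkers.
#' @param n_steps simulation horizon (time steps).
#' @param seed integer seed.
#' @return a tibble of class `ms_trajectories`: `id`, `step` (0 =
#'   start), `x`, `y`; the pattern is attached as an attribute.
#' @export
simulate_pattern <- function(pattern, n_individuals, n_steps = 100, seed = 1) {
  stopifnot(inherits(pattern, "ms_pattern"))
  if (n_individuals < 1) abort("`n_individuals` must be at least 1.")
  local_rng(seed)
  m <- n_individuals * n_steps
  if (pattern$speed_mean == 0 || pattern$speed_sd == 0) {
    lens <- rep(pattern$speed_mean, m)
  } else {
    shp <- (pattern$speed_mean / pattern$speed_sd)^2
    lens <- rgamma(m, shp, scale = pattern$speed_sd^2 / pattern$speed_mean)
  }
  if (pattern$mix_weight >= 1) {
    turns <- rvonmises(m, pattern$angle_mean, pattern$angle_conc)
  } else {
    pick1 <- runif(m) < pattern$mix_weight
    turns <- numeric(m)
    turns[pick1] <- rvonmises(sum(pick1), pattern$angle_mean, pattern$angle_conc)
    turns[!pick1] <- rvonmises(sum(!pick1), pattern$angle_mean2,
                               pattern$angle_conc2)
  }
  lens <- matrix(lens, nrow = n_steps)
  turns <- matrix(turns, nrow = n_steps)
  h0 <- runif(n_individuals, -pi, pi)
  headings <- matrix(apply(turns, 2, cumsum), nrow = n_steps) +
    rep(h0, each = n_steps)
  x <- matrix(apply(lens * cos(headings), 2, cumsum), nrow = n_steps)
  y <- matrix(apply(lens * sin(headings), 2, cumsum), nrow = n_steps)
  out <- tibble::tibble(
    id = rep(seq_len(n_individuals), each = n_steps + 1),
    step = rep(0:n_steps, n_individuals),
    x = as.numeric(rbind(0, x)),
    y = as.numeric(rbind(0, y))
  )
  class(out) <- c("ms_trajectories", class(out))
  attr(out, "pattern") <- pattern
  attr(out, "n_steps") <- n_steps
  out
}

#' Ring-connection summary of simulated trajectories
#'
#' An individual "connects" if any of its positions reaches a distance of
#' at least `ring_radius` from the origin within the simulated horizon.
#'
#' @param trajectories output of [simulate_pattern()].
#' @param ring_radius ring distance from the origin (km), `> 0`.
#' @return a list of class `ms_connectivity`: `summary` (one-row tibble
#'   with `pattern`, `n_individuals`, `n_steps`, `ring_radius`,
#'   `prop_connected`) and `individuals` (tibble with `id`,
#'   `first_hit_step`, `connected`).
#' @export
ring_connection <- function(trajectories, ring_radius) {
  if (ring_radius <= 0) abort("`ring_radius` must be positive.")
  pat <- attr(trajectories, "pattern")
  ind <- trajectories |>
    dplyr::mutate(dist = sqrt(.data$x^2 + .data$y^2)) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      first_hit_step = if (any(.data$dist >= ring_radius))
        min(.data$step[.data$dist >= ring_radius]) else NA_integer_,
      connected = !is.na(.data$first_hit_step),
      .groups = "drop"
    )
  structure(
    list(
      summary = tibble::tibble(
        pattern = if (is.null(pat)) NA_character_ else pat$name,
        n_individuals = nrow(ind),
        n_steps = attr(trajectories, "n_steps") %||%
          max(trajectories$step),
        ring_radius = ring_radius,
        prop_connected = mean(ind$connected)
      ),
      individuals = ind
    ),
    class = "ms_connectivity"
  )
}

#' @export
print.ms_connectivity <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
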