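#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector with every value in `(-pi, pi]`.
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

#' von Mises density
#'
#' Density of the von Mises distribution with mean direction `mu` and
#' concentration `kappa`, evaluated with exponentially scaled Bessel
#' functions so that large concentrations do not overflow.
#'
#' @param x angles in radians.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter, `>= 0`.
#' @param log return the log density?
#' @return numeric vector of (log) densities.
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  if (kappa < 0) abort("`kappa` must be non-negative.")
  log_i0s <- if (kappa > 1e5) {
    # large-argument expansion, where R's Bessel routines degrade
    -0.5 * log(2 * pi * kappa) + log1p(1 / (8 * kappa))
  } else {
    log(besselI(kappa, 0, expon.scaled = TRUE))
  }
  lognorm <- log(2 * pi) + log_i0s + kappa
  ld <- kappa * cos(x - mu) - lognorm
  if (log) ld else exp(ld)
}

#' von Mises cumulative distribution on (-pi, pi]
#'
#' CDF anchored at `-pi`, computed by trapezoidal integration on a dense
#' grid with linear interpolation between grid points.
#'
#' @inheritParams dvonmises
#' @param n_grid number of grid cells for the quadrature.
#' @return numeric vector of probabilities `F(x) = P(theta <= x)`.
#' @export
pvonmises <- function(x, mu = 0, kappa = 1, n_grid = 16384) {
  grid <- seq(-pi, pi, length.out = n_grid + 1)
  dens <- dvonmises(grid, mu, kappa)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  xw <- ifelse(x >= -pi & x <= pi, x, wrap_angle(x))
  approx(grid, cdf, xout = xw, rule = 2)$y
}

#' Draw from a von Mises distribution
#'
#' Best--Fisher rejection sampling, vectorised by batch rejection. Falls
#' back to the circular uniform when `kappa` is numerically zero.
#'
#' @param n number of draws.
#' @inheritParams dvonmises
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-9) return(wrap_angle(runif(n, -pi, pi) + mu))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.4))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[keep] - 0.5) * acos(pmin(1, pmax(-1, f[keep])))
    out <- c(out, theta)
  }
  wrap_angle(out[seq_len(n)] + mu)
}

#' Convert between von Mises concentration and circular standard deviation
#'
#' The circular SD of a von Mises distribution is
#' `sqrt(-2 * log(rho))` with mean resultant length
#' `rho = I1(kappa) / I0(kappa)`. The inverse direction solves for `kappa`
#' by bracketed root finding.
#'
#' @param value a positive concentration (for `direction = "to_sd"`) or a
#'   positive circular SD in radians (for `direction = "to_kappa"`).
#' @param direction `"to_sd"` or `"to_kappa"`.
#' @return the converted value.
#' @export
#' @examples
#' circular_sd_kappa(circular_sd_kappa(2, "to_sd"), "to_kappa")
circular_sd_kappa <- function(value, direction = c("to_sd", "to_kappa")) {
  direction <- match.arg(direction)
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) || value <= 0)
    abort("`value` must be a single positive number.")
  to_sd <- function(kappa) {
    # R's Bessel routines degrade beyond ~1e5; use the large-argument
    # expansion of I1/I0 there
    rho <- if (kappa > 1e5) {
      1 - 1 / (2 * kappa) - 1 / (8 * kappa^2) - 1 / (8 * kappa^3)
    } else {
      besselI(kappa, 1, expon.scaled = TRUE) /
        besselI(kappa, 0, expon.scaled = TRUE)
    }
    sqrt(-2 * log(rho))
  }
  if (direction == "to_sd") return(to_sd(value))
  f <- function(k) to_sd(k) - value
  lo <- 1e-8
  hi <- 10
  while (f(hi) > 0 && hi < 1e9) hi <- hi * 10
  if (f(lo) < 0) abort("circular SD too large to invert.")
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}
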