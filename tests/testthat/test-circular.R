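test_that("angles wrap into (-pi, pi]", {
  x <- c(0, pi, -pi, 3 * pi / 2, -3 * pi / 2, 7.5, -12.3)
  w <- wrap_angle(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(w[1:3], c(0, pi, pi))
  expect_equal(sin(w), sin(x), tolerance = 1e-12)
  expect_equal(cos(w), cos(x), tolerance = 1e-12)
})

test_that("von Mises density integrates to one and matches the Bessel form", {
  for (kappa in c(0.3, 2, 50)) {
    f <- integrate(dvonmises, -pi, pi, mu = 0.7, kappa = kappa,
                   rel.tol = 1e-10)
    expect_equal(f$value, 1, tolerance = 1e-8)
  }
  # large concentration stays finite (exponentially scaled Bessel)
  expect_true(is.finite(dvonmises(0, 0, 1e6)))
})

test_that("von Mises CDF matches quadrature of the density", {
  for (kappa in c(0.5, 3)) {
    mu <- -0.4
    for (x in c(-2.5, -0.3, 0.9, 3)) {
      direct <- integrate(dvonmises, -pi, x, mu = mu, kappa = kappa,
                          rel.tol = 1e-10)$value
      expect_lt(abs(pvonmises(x, mu, kappa) - direct), 1e-6)
    }
  }
  expect_equal(pvonmises(pi, 0.3, 2), 1, tolerance = 1e-9)
  expect_equal(pvonmises(-pi, 0.3, 2), 0, tolerance = 1e-9)
})

test_that("von Mises sampler reproduces the mean resultant length", {
  set.seed(11)
  for (kappa in c(0.4, 2, 12)) {
    x <- rvonmises(40000, 0.5, kappa)
    expect_true(all(x > -pi & x <= pi))
    rho_hat <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
    rho <- besselI(kappa, 1, expon.scaled = TRUE) /
      besselI(kappa, 0, expon.scaled = TRUE)
    expect_equal(rho_hat, rho, tolerance = 4 / sqrt(40000) / rho)
    mdir <- atan2(mean(sin(x)), mean(cos(x)))
    expect_equal(mdir, 0.5, tolerance = 0.05)
  }
})

test_that("kappa and circular SD convert as an inverse pair", {
  for (kappa in c(0.1, 0.5, 2, 10, 50)) {
    sd_k <- circular_sd_kappa(kappa, "to_sd")
    expect_equal(circular_sd_kappa(sd_k, "to_kappa"), kappa,
                 tolerance = 1e-8)
  }
  # concentration limit: circular SD ~ 1/sqrt(kappa) -> ~1e-3 at 1e6
  expect_lt(circular_sd_kappa(1e6, "to_sd"), 1.01e-3)
  expect_error(circular_sd_kappa(-1, "to_sd"), "positive")
})

test_that("published angle dispersion round-trips through generation", {
  # dispersion reported for the intermediate movement state
  kappa <- circular_sd_kappa(1.59, "to_kappa")
  set.seed(21)
  x <- rvonmises(60000, 0, kappa)
  rho_hat <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
  expect_equal(sqrt(-2 * log(rho_hat)), 1.59, tolerance = 0.02)
})
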