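mk_fixes <- function(mins, x, y, id = "a",
                     t0 = as.POSIXct("2019-03-01 06:00:00", tz = "UTC")) {
  tibble::tibble(id = id, timestamp = t0 + mins * 60, x_km = x, y_km = y)
}

test_that("regularisation is the identity on an exact grid", {
  fx <- mk_fixes(seq(0, 400, by = 80), x = 1:6, y = 6:1)
  out <- regularize_fixes(fx, 80, 5)
  expect_equal(out$timestamp, fx$timestamp)
  expect_equal(out$x_km, fx$x_km)
  expect_equal(out$y_km, fx$y_km)
})

test_that("a double interval inserts one missing slot", {
  fx <- mk_fixes(c(0, 80, 240), x = c(0, 1, 2), y = 0)
  out <- regularize_fixes(fx, 80, 5)
  expect_equal(nrow(out), 4)
  expect_true(is.na(out$x_km[3]))
  expect_equal(out$x_km[c(1, 2, 4)], c(0, 1, 2))
})

test_that("nearest fix within tolerance fills each slot", {
  fx <- mk_fixes(c(0, 78, 161), x = c(10, 20, 30), y = 0)
  out <- regularize_fixes(fx, 80, 5)
  expect_equal(nrow(out), 3)
  expect_equal(out$x_km, c(10, 20, 30))
  # a fix 10 min off the grid is dropped, not snapped
  fx2 <- mk_fixes(c(0, 90, 160), x = c(10, 20, 30), y = 0)
  out2 <- regularize_fixes(fx2, 80, 5)
  expect_true(is.na(out2$x_km[2]))
  expect_equal(out2$x_km[3], 30)
})

test_that("duplicate timestamps are rejected", {
  fx <- mk_fixes(c(0, 80, 80), x = 1:3, y = 0)
  expect_error(regularize_fixes(fx), "duplicate")
})

test_that("step lengths and turning angles follow plane geometry", {
  fx <- mk_fixes(c(0, 80, 160), x = c(0, 1, 2), y = c(0, 0, 0))
  st <- steps_and_angles(fx)
  expect_equal(st$step_km, c(1, 1))
  expect_true(is.na(st$angle_rad[1]))
  expect_equal(st$angle_rad[2], 0)

  fx2 <- mk_fixes(c(0, 80, 160), x = c(0, 1, 1), y = c(0, 0, 1))
  st2 <- steps_and_angles(fx2)
  expect_equal(st2$angle_rad[2], pi / 2)  # left turn is positive

  fx3 <- mk_fixes(c(0, 80, 160), x = c(0, 1, 1), y = c(0, 0, -1))
  expect_equal(steps_and_angles(fx3)$angle_rad[2], -pi / 2)

  # two fixes: one step, angle undefined
  st4 <- steps_and_angles(mk_fixes(c(0, 80), x = c(0, 3), y = c(0, 4)))
  expect_equal(nrow(st4), 1)
  expect_equal(st4$step_km, 5)
  expect_true(is.na(st4$angle_rad))
})

test_that("angles adjacent to a missing position are undefined", {
  fx <- mk_fixes(seq(0, 320, by = 80), x = c(0, 1, NA, 3, 4), y = 0)
  st <- steps_and_angles(fx)
  expect_equal(nrow(st), 4)
  expect_true(all(is.na(st$step_km[2:3])))
  expect_true(all(is.na(st$angle_rad[2:4])))
})

test_that("the minimum-step filter marks but never deletes records", {
  fx <- mk_fixes(seq(0, 800, by = 80),
                 x = cumsum(c(0, 0.5, 0.1, 0.6, 0.05, 0.7, 0.4, 0.15, 0.5,
                              0.6, 0.3))[1:11],
                 y = 0)
  st <- steps_and_angles(fx)
  out <- filter_min_step(st, 0.2)
  expect_equal(nrow(out), nrow(st))
  expect_equal(sum(is.na(out$step_km)), 3)
  # the angle using a removed displacement is missing on both sides
  dropped <- which(st$step_km < 0.2)
  expect_true(all(is.na(out$angle_rad[dropped])))
  expect_true(all(is.na(out$angle_rad[pmin(dropped + 1, nrow(out))])))

  expect_equal(filter_min_step(st, 0), st)
  all_na <- filter_min_step(st, 10)
  expect_equal(nrow(all_na), nrow(st))
  expect_true(all(is.na(all_na$step_km)))
})

test_that("covariates come from the step-start cell and the Julian day", {
  ls <- make_landscape(5, 20, 20)
  t_den <- as.POSIXct("2019-01-01", tz = "UTC") + (160 - 1) * 86400
  t_edge <- as.POSIXct("2019-01-01", tz = "UTC") + (220 - 1) * 86400
  t_out <- as.POSIXct("2019-01-01", tz = "UTC") + (221 - 1) * 86400
  st <- tibble::tibble(
    id = "a", t = c(t_den, t_edge, t_out),
    x_km = c(4.5, 4.5, 10.2), y_km = c(7.5, 7.5, 3.3),
    step_km = 1, angle_rad = 0
  )
  out <- extract_covariates(st, ls)
  expect_equal(out$hfi_raw[1], ls$footprint[8, 5])
  expect_equal(out$in_park[3], as.integer(ls$park_mask[4, 11]))
  expect_equal(out$denning, c(1L, 1L, 0L))

  st_bad <- dplyr::mutate(st, x_km = c(4.5, 50, 10.2))
  expect_error(extract_covariates(st_bad, ls), "outside")
})

test_that("standardisation centres and scales by the population SD", {
  st <- tibble::tibble(id = "a", t = Sys.time() + 1:2, x_km = 0, y_km = 0,
                       step_km = 1, angle_rad = 0, hfi_raw = c(2, 16))
  out <- standardize_hfi(st)
  expect_equal(out$steps$hfi_std, c(-1, 1))
  expect_equal(out$stats$mean, 9)
  expect_equal(out$stats$sd, 7)

  set.seed(4)
  st2 <- tibble::tibble(id = "a", t = Sys.time() + 1:50, x_km = 0, y_km = 0,
                        step_km = 1, angle_rad = 0, hfi_raw = runif(50, 2, 16))
  out2 <- standardize_hfi(st2)
  expect_equal(mean(out2$steps$hfi_std), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(out2$steps$hfi_std^2)), 1, tolerance = 1e-12)

  # stored stats map the mean onto zero
  reap <- standardize_hfi(dplyr::mutate(st2, hfi_raw = out2$stats$mean),
                          stats = out2$stats)
  expect_true(all(abs(reap$steps$hfi_std) < 1e-12))

  expect_error(standardize_hfi(dplyr::mutate(st2, hfi_raw = 5)), "variance")
})

test_that("the pressure score uses a base-10 log and saturates at 1000", {
  expect_equal(pressure_score(0), 0)
  expect_equal(pressure_score(9), 3.333)
  expect_equal(pressure_score(5000), pressure_score(1000))
  expect_equal(pressure_score(1000), 3.333 * log10(1001))
  expect_error(pressure_score(-1), "non-negative")
})

test_that("steps and angles recover the generator's drawn values", {
  spec <- toy_spec_3()
  ls <- make_landscape(31, 500, 500)
  tr <- simulate_tracks(spec, ls, n_tracks = 2, n_steps = 150, seed = 5)
  st <- steps_and_angles(dplyr::rename(tr, timestamp = time))
  drawn <- tr |>
    dplyr::group_by(id) |>
    dplyr::slice(-dplyr::n()) |>
    dplyr::ungroup()
  # steps recoverable wherever the step itself was not reflected
  usable_step <- !drawn$reflected
  expect_equal(st$step_km[usable_step], drawn$step_km[usable_step],
               tolerance = 1e-9)
  # angles need the previous displacement intact and a previous heading
  first_of_id <- !duplicated(drawn$id)
  usable_angle <- usable_step & !first_of_id &
    !c(TRUE, head(drawn$reflected, -1))
  expect_gt(sum(usable_angle), 200)
  expect_equal(st$angle_rad[usable_angle], drawn$angle_rad[usable_angle],
               tolerance = 1e-9)
})
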