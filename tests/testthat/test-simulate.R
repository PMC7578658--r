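test_that("tracks are bit-reproducible and structurally sound", {
  sp <- toy_spec_3()
  ls <- make_landscape(12, 80, 80)
  a <- simulate_tracks(sp, ls, n_tracks = 2, n_steps = 50, seed = 9)
  b <- simulate_tracks(sp, ls, n_tracks = 2, n_steps = 50, seed = 9)
  expect_identical(a, b)
  c <- simulate_tracks(sp, ls, n_tracks = 2, n_steps = 50, seed = 10)
  expect_false(identical(a$x_km, c$x_km))

  per <- dplyr::count(a, id)
  expect_equal(per$n, rep(51, 2))
  gaps <- a |> dplyr::group_by(id) |>
    dplyr::summarise(ok = all(diff(as.numeric(time)) == 80 * 60))
  expect_true(all(gaps$ok))
  expect_true(all(a$state %in% 1:3))
  ext <- landscape_extent(ls)
  expect_true(all(a$x_km >= ext["xmin"] & a$x_km <= ext["xmax"]))
  expect_true(all(a$y_km >= ext["ymin"] & a$y_km <= ext["ymax"]))
})

test_that("empirical transition frequencies match an intercept-only matrix", {
  sp <- hmm_spec(c(0.3, 1.2, 3.1), c(0.12, 0.5, 1), rep(0, 3),
                 c(0.6, 1.5, 4),
                 beta = matrix(c(log(0.10 / 0.75), log(0.15 / 0.75),
                                 log(0.20 / 0.70), log(0.10 / 0.70),
                                 log(0.05 / 0.80), log(0.15 / 0.80)),
                               nrow = 1))
  truth <- transition_matrix(sp)
  expect_equal(truth[1, ], c(0.75, 0.10, 0.15), tolerance = 1e-12)
  ls <- make_landscape(13, 600, 600)
  tr <- simulate_tracks(sp, ls, n_tracks = 50, n_steps = 1000, seed = 14)
  st <- tr |> dplyr::group_by(id) |>
    dplyr::summarise(from = list(head(state, -2)), to = list(state[2:(dplyr::n() - 1)]))
  from <- unlist(st$from); to <- unlist(st$to)
  for (i in 1:3) {
    n_i <- sum(from == i)
    for (j in 1:3) {
      p_hat <- sum(from == i & to == j) / n_i
      se <- sqrt(truth[i, j] * (1 - truth[i, j]) / n_i)
      expect_lt(abs(p_hat - truth[i, j]), 3 * se + 1e-12)
    }
  }
})

test_that("single-state step lengths match the generating gamma", {
  sp <- hmm_spec(1.2, 0.6, 0, 1)
  ls <- make_landscape(15, 800, 800)
  tr <- simulate_tracks(sp, ls, n_tracks = 4, n_steps = 1500, seed = 16)
  drawn <- tr$step_km[!is.na(tr$step_km)]
  n <- length(drawn)
  expect_lt(abs(mean(drawn) - 1.2), 3 * 0.6 / sqrt(n))
  expect_lt(abs(sd(drawn) - 0.6), 3 * 0.6 / sqrt(2 * n))
})

test_that("per-state emissions match their generating distributions", {
  sp <- toy_spec_3()
  ls <- make_landscape(17, 900, 900)
  tr <- simulate_tracks(sp, ls, n_tracks = 6, n_steps = 1200, seed = 18)
  em <- sp$emissions
  for (k in 1:3) {
    rows <- which(tr$state == k & !is.na(tr$step_km))
    s <- tr$step_km[rows]
    a <- tr$angle_rad[rows]
    n <- length(s)
    expect_lt(abs(mean(s) - em$step_mean[k]),
              3 * em$step_sd[k] / sqrt(n))
    expect_lt(abs(sd(s) - em$step_sd[k]), 4 * em$step_sd[k] / sqrt(2 * n))
    rho_hat <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
    sd_hat <- sqrt(-2 * log(rho_hat))
    sd_true <- circular_sd_kappa(em$angle_conc[k], "to_sd")
    expect_lt(abs(sd_hat - sd_true), 4 * sd_true / sqrt(2 * n))
  }
})

test_that("dwell times follow the self-transition probability", {
  sp <- hmm_spec(c(0.3, 1.2, 3.1), c(0.12, 0.5, 1), rep(0, 3), c(0.6, 1.5, 4),
                 diag_prob = 0.8)
  ls <- make_landscape(19, 700, 700)
  tr <- simulate_tracks(sp, ls, n_tracks = 20, n_steps = 800, seed = 20)
  runs <- tr |> dplyr::group_by(id) |>
    dplyr::summarise(r = list(rle(head(state, -1))$lengths))
  lens <- unlist(runs$r)
  # expected dwell 1 / (1 - 0.8) = 5; geometric SD = sqrt(0.8) / 0.2
  se <- (sqrt(0.8) / 0.2) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 5), 3 * se)
})

test_that("a nearly deterministic walk travels in a straight line", {
  s <- 0.7
  sp <- hmm_spec(s, 1e-6, 0, 1e6)
  ls <- make_landscape(21, 800, 800)
  tr <- simulate_tracks(sp, ls, n_tracks = 1, n_steps = 100, seed = 22)
  if (!any(tr$reflected, na.rm = TRUE)) {
    d <- sqrt(diff(range(tr$x_km))^2 + diff(range(tr$y_km))^2)
    expect_equal(d, 100 * s, tolerance = 1e-3)
  }
  # drawn steps are essentially constant either way
  expect_equal(unique(round(tr$step_km[!is.na(tr$step_km)], 4)), s)
})

test_that("resting injection shortens the chosen steps and nothing else", {
  # long-stepping states, so natural sub-0.2 km steps are essentially absent
  sp <- hmm_spec(c(1.5, 3, 5), c(0.3, 0.5, 0.8), rep(0, 3), c(1, 1, 1),
                 diag_prob = 0.8)
  ls <- make_landscape(23, 800, 800)
  tr <- simulate_tracks(sp, ls, n_tracks = 4, n_steps = 250, seed = 24)

  same <- inject_resting(tr, 0, seed = 1)
  expect_equal(same$x_km, tr$x_km)
  expect_equal(same$y_km, tr$y_km)

  fx <- inject_resting(tr, 0.2, seed = 2)
  expect_identical(fx, inject_resting(tr, 0.2, seed = 2))
  st <- steps_and_angles(fx)
  n_steps <- 4 * 250
  n_short <- sum(st$step_km < 0.2, na.rm = TRUE)
  se <- sqrt(n_steps * 0.2 * 0.8)
  expect_lt(abs(n_short - 0.2 * n_steps), 3 * se)
  expect_error(inject_resting(tr, 1.2, 1), "rest_prob")
})

test_that("fix tables round-trip through CSV", {
  sp <- toy_spec_3()
  ls <- make_landscape(25, 100, 100)
  tr <- simulate_tracks(sp, ls, n_tracks = 1, n_steps = 20, seed = 26)
  fx <- inject_resting(tr, 0.1, seed = 3)
  path <- file.path(withr::local_tempdir(), "fixes.csv")
  write_fixes(fx, path)
  back <- read_fixes(path)
  expect_equal(back$id, fx$id)
  expect_equal(as.numeric(back$timestamp), as.numeric(fx$timestamp))
  expect_equal(back$x_km, fx$x_km, tolerance = 1e-12)
  expect_equal(back$true_state, fx$true_state)
})
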