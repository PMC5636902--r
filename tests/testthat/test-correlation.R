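test_that("MSD matches closed forms and the double-loop oracle", {
  n <- 50
  const <- new_trajectory(rep(3, n), rep(-1, n))
  expect_true(all(msd(const, max_lag = 10)$value == 0))

  ball <- new_trajectory(0.25 * (1:n), rep(0, n))
  mb <- msd(ball, max_lag = 10)
  expect_equal(mb$value, 0.25^2 * mb$lag^2, tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:5) {
    tr <- random_traj(50)
    m <- msd(tr, max_lag = 20)
    expect_equal(m$value, msd_naive(tr$x, tr$y, 20), tolerance = 1e-12)
    # per-component curves sum to the 2-D curve
    mx <- msd(tr, max_lag = 20, component = "x")
    my <- msd(tr, max_lag = 20, component = "y")
    expect_equal(mx$value + my$value, m$value, tolerance = 1e-12)
  }
  expect_error(msd(random_traj(20), max_lag = 20), "smaller")
})

test_that("DACF is normalised, equals 1 for ballistic motion, and matches its oracle", {
  n <- 80
  ball <- new_trajectory(1:n, 2 * (1:n))
  db <- dacf(ball, k = 5, max_lag = 20)
  expect_equal(db$value, rep(1, 21), tolerance = 1e-12)

  set.seed(12)
  for (rep in 1:5) {
    tr <- random_traj(80)
    d <- dacf(tr, k = 5, max_lag = 20)
    expect_equal(d$value[d$lag == 0], 1)
    expect_equal(d$value, dacf_naive(tr$x, tr$y, 5, 20), tolerance = 1e-12)
  }
  expect_error(dacf(random_traj(20), k = 10, max_lag = 15), "too short")
})

test_that("MSD and DACF are invariant under translation and rotation", {
  set.seed(13)
  tr <- random_traj(120)
  theta <- 0.7
  rot <- new_trajectory(cos(theta) * tr$x - sin(theta) * tr$y,
                        sin(theta) * tr$x + cos(theta) * tr$y)
  shift <- dplyr::mutate(tr, x = x + 42, y = y - 17)
  expect_equal(msd(tr, max_lag = 15)$value, msd(shift, max_lag = 15)$value,
               tolerance = 1e-9)
  expect_equal(msd(tr, max_lag = 15)$value, msd(rot, max_lag = 15)$value,
               tolerance = 1e-9)
  expect_equal(dacf(tr, k = 5, max_lag = 15)$value,
               dacf(rot, k = 5, max_lag = 15)$value, tolerance = 1e-9)
})

test_that("curve averaging reduces to the identity and detects grid mismatches", {
  set.seed(14)
  c1 <- msd(random_traj(60), max_lag = 10)
  avg1 <- average_curves(list(c1))
  expect_equal(avg1$value, c1$value)
  expect_equal(avg1$sd, rep(0, 10))

  avg2 <- average_curves(list(c1, c1))
  expect_equal(avg2$value, c1$value)
  expect_equal(avg2$sd, rep(0, 10))
  expect_true(all(avg2$n == 2L))

  c2 <- msd(random_traj(60), max_lag = 8)
  expect_error(average_curves(list(c1, c2)), "lag grid")

  # averaging a long tibble with a trial column matches the manual mean
  c3 <- msd(random_traj(60), max_lag = 10)
  long <- dplyr::bind_rows(dplyr::mutate(c1, trial = 1), dplyr::mutate(c3, trial = 2))
  avg3 <- average_curves(long)
  expect_equal(avg3$value, (c1$value + c3$value) / 2, tolerance = 1e-12)
})

test_that("scaling-exponent fits recover exact power laws", {
  lags <- 1:100
  curve2 <- tibble::tibble(lag = lags, lag_ms = lags * 2, value = 0.3 * lags^2)
  f2 <- fit_scaling_exponent(curve2, c(2, 12))
  expect_equal(f2$alpha, 2, tolerance = 1e-9)

  curve1 <- tibble::tibble(lag = lags, lag_ms = lags * 2, value = 5 * lags)
  f1 <- fit_scaling_exponent(curve1, c(120, 1200) / 10)
  expect_equal(f1$alpha, 1, tolerance = 1e-9)

  # endpoints are inclusive: the 2-12 ms window at 2 ms sampling holds 6 lags
  expect_equal(f2$n_lags, 6)
  expect_error(fit_scaling_exponent(curve2, c(2, 5.9)), "fewer than 3")
})

test_that("oscillation metrics find the first positive maximum after the zero crossing", {
  lag <- 0:300
  cosine <- tibble::tibble(lag = lag, lag_ms = lag * 2,
                           value = cos(2 * pi * lag / 100))
  om <- oscillation_metrics(cosine)
  expect_true(om$detected)
  expect_equal(om$first_max_lag_ms, 200) # period of 100 samples = 200 ms
  expect_equal(om$delay_lower_ms, 50)
  expect_equal(om$delay_upper_ms, 100)

  decay <- tibble::tibble(lag = lag, lag_ms = lag * 2, value = exp(-lag / 50))
  om2 <- oscillation_metrics(decay)
  expect_false(om2$detected) # no zero crossing: a first-class outcome, not an error

  # decays below zero and stays there: crossing but no positive maximum
  dip <- tibble::tibble(lag = lag, lag_ms = lag * 2, value = -1 + exp(-lag / 50) * 2)
  expect_false(oscillation_metrics(dip)$detected)

  short <- cosine[cosine$lag_ms < 300, ]
  expect_error(oscillation_metrics(short), "400 ms")
})

test_that("delay bounds invert the period-delay band of delayed feedback systems", {
  expect_equal(delay_bounds(100), c(lower = 25, upper = 50))
  expect_equal(delay_bounds(200), c(lower = 50, upper = 100))
  b <- delay_bounds(c(100, 200))
  expect_equal(unname(b[, "lower"]), c(25, 50))
})
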