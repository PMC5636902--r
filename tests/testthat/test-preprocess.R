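dt <- 0.002

test_that("five-point velocity estimator is exact on linear and quadratic motion", {
  n <- 40
  lin <- new_trajectory(3 * (1:n), rep(0, n), dt = dt)
  v <- estimate_velocity(lin)
  expect_equal(nrow(v), n - 2)
  expect_equal(v$sample, 2:(n - 1))
  expect_true(all(abs(v$vx - 3 / dt) < 1e-9)) # both formulas give the slope

  quad <- new_trajectory((1:n)^2, rep(0, n), dt = dt)
  vq <- estimate_velocity(quad)
  # symbolic expansion of the five-point sum on x_i = i^2 gives 12 i / (6 dt)
  interior <- vq$sample >= 3 & vq$sample <= n - 2
  expect_equal(vq$vx[interior], 2 * vq$sample[interior] / dt, tolerance = 1e-12)
  # boundary samples use the central difference, not the five-point form
  expect_equal(vq$vx[vq$sample == 2], (quad$x[3] - quad$x[1]) / (2 * dt))
  expect_equal(vq$vx[vq$sample == n - 1], (quad$x[n] - quad$x[n - 2]) / (2 * dt))
})

test_that("velocity estimation is linear in the trajectory", {
  set.seed(5)
  a <- random_traj(30); b <- random_traj(30)
  combo <- new_trajectory(2 * a$x - 3 * b$x, 2 * a$y - 3 * b$y)
  v <- estimate_velocity(combo)
  va <- estimate_velocity(a); vb <- estimate_velocity(b)
  expect_equal(v$vx, 2 * va$vx - 3 * vb$vx, tolerance = 1e-9)
  expect_equal(v$vy, 2 * va$vy - 3 * vb$vy, tolerance = 1e-9)
})

test_that("velocity integration matches a naive loop and telescopes constants", {
  set.seed(6)
  vel <- tibble::tibble(vx = rnorm(50), vy = rnorm(50))
  out <- integrate_velocity(vel, c(1.5, -2), dt = dt)
  expect_equal(nrow(out), 52)
  # naive loop oracle
  for (i in c(1, 2, 10, 52)) {
    expected <- 1.5 + if (i > 2) dt * sum(vel$vx[1:(i - 2)]) else 0
    expect_equal(out$x[i], expected, tolerance = 1e-12)
  }
  # constant velocity: linear from the second sample on
  cst <- integrate_velocity(tibble::tibble(vx = rep(2, 20), vy = rep(0, 20)),
                            c(0, 0), dt = dt)
  expect_equal(diff(cst$x[2:22]), rep(2 * dt, 20), tolerance = 1e-12)
})

test_that("smoothing reproduces linear motion (one-sample shift) and keeps length", {
  n <- 60
  lin <- new_trajectory(5 * (1:n), -2 * (1:n), dt = dt)
  sm <- smooth_trajectory(lin)
  expect_equal(nrow(sm), n)
  # the cumulative-sum convention starts the smoothed series at x_1 twice,
  # reproducing the linear motion with a one-sample index shift
  expect_equal(sm$x[3:n], lin$x[2:(n - 1)], tolerance = 1e-9)
  expect_equal(diff(sm$y[2:n]), rep(-2, n - 2), tolerance = 1e-9)
})

test_that("elliptical threshold detection matches the run-scan oracle", {
  set.seed(7)
  for (rep in 1:20) {
    vel <- tibble::tibble(sample = 2:61, vx = rnorm(60), vy = rnorm(60))
    lambda <- 1.2 # low threshold so episodes occur
    eps <- detect_microsaccades(vel, lambda = lambda, min_samples = 3)
    sx <- sqrt(median(vel$vx^2) - median(vel$vx)^2)
    sy <- sqrt(median(vel$vy^2) - median(vel$vy)^2)
    above <- (vel$vx / (lambda * sx))^2 + (vel$vy / (lambda * sy))^2 > 1
    oracle <- runs_naive(above, 3)
    expect_equal(eps$onset, vel$sample[oracle$onset])
    expect_equal(eps$end, vel$sample[oracle$end])
  }
})

test_that("episodes need at least min_samples consecutive suprathreshold samples", {
  base <- tibble::tibble(sample = 2:41, vx = rnorm(40, 0, 0.1), vy = rnorm(40, 0, 0.1))
  spike3 <- base; spike3$vx[10:12] <- 50
  spike2 <- base; spike2$vx[10:11] <- 50
  expect_equal(nrow(detect_microsaccades(spike3, lambda = 5)), 1)
  expect_equal(nrow(detect_microsaccades(spike2, lambda = 5)), 0)
})

test_that("detection is invariant under constant position offsets and flags degenerate input", {
  set.seed(8)
  traj <- random_traj(200)
  traj$x[50:60] <- traj$x[50:60] + cumsum(rep(0.5, 11)) # injected fast drift
  shifted <- dplyr::mutate(traj, x = x + 100, y = y - 7)
  expect_equal(detect_microsaccades(traj), detect_microsaccades(shifted))

  const <- new_trajectory(rep(1, 30), rep(2, 30))
  expect_error(detect_microsaccades(const), class = "femwalk_degenerate_threshold")
})

test_that("binocular pairing applies the strict overlap criterion literally", {
  ep <- function(onset, end) tibble::tibble(onset = onset, end = end)
  # touching endpoints: r_onset < l_end fails (15 < 15 is false) -> rejected
  expect_equal(nrow(pair_binocular(ep(10, 15), ep(15, 20))), 0)
  # two-sample overlap -> union episode
  out <- pair_binocular(ep(10, 15), ep(14, 20))
  expect_equal(out$onset, 10)
  expect_equal(out$end, 20)
  # disjoint -> empty
  expect_equal(nrow(pair_binocular(ep(10, 15), ep(30, 35))), 0)
})

test_that("binocular pairing is symmetric in its arguments", {
  set.seed(9)
  for (rep in 1:10) {
    onsets <- sort(sample(1:200, 5))
    l <- tibble::tibble(onset = onsets, end = onsets + sample(2:8, 5, TRUE))
    onsets_r <- sort(sample(1:200, 5))
    r <- tibble::tibble(onset = onsets_r, end = onsets_r + sample(2:8, 5, TRUE))
    expect_equal(pair_binocular(l, r), pair_binocular(r, l))
  }
})

test_that("microsaccade removal shortens the trajectory and defaults to smoothing", {
  set.seed(10)
  traj <- random_traj(100)
  none <- tibble::tibble(onset = integer(), end = integer())
  expect_equal(remove_microsaccades(traj, none), smooth_trajectory(traj))

  ep <- tibble::tibble(onset = c(20L, 50L), end = c(24L, 52L)) # 5 + 3 samples
  out <- remove_microsaccades(traj, ep)
  expect_equal(nrow(out), 100 - 8)

  bad <- tibble::tibble(onset = 1L, end = 5L) # velocity indices start at 2
  expect_error(remove_microsaccades(traj, bad), "2..N-1")
})
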