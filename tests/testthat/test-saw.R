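test_that("lattice potentials match hand-evaluated values and symmetries", {
  p <- saw_params() # L = 51, centre (26, 26)
  expect_equal(potential_u(26, 26, p), 0)
  expect_equal(potential_u(1, 26, p), 51 * (25 / 26)^2, tolerance = 1e-12)
  expect_equal(51 * (25 / 26)^2, 47.15237, tolerance = 1e-6) # frozen hand value
  # mirror symmetry about the centre
  expect_equal(potential_u(6, 14, p), potential_u(2 * 26 - 6, 14, p))
  expect_equal(potential_u(6, 14, p), potential_u(6, 2 * 26 - 14, p))

  # microsaccadic potential: zero on the axes, positive elsewhere
  expect_equal(potential_u1(26, 3, p), 0)
  expect_equal(potential_u1(44, 26, p), 0)
  expect_equal(potential_u1(1, 1, p), 2 * 51 * (25 / 26)^4, tolerance = 1e-12)
  expect_equal(2 * 51 * (25 / 26)^4, 87.19006, tolerance = 1e-5) # frozen hand value
  ij <- expand.grid(i = seq(1, 51, 7), j = seq(1, 51, 7))
  expect_true(all(potential_u1(ij$i, ij$j, p) >= 0))

  # anisotropic slopes separate the components
  pa <- saw_params(lambda_hor = 0.9, lambda_ver = 1.1)
  expect_equal(potential_u(1, 26, pa), 0.9 * 51 * (25 / 26)^2)
  expect_equal(potential_u(26, 1, pa), 1.1 * 51 * (25 / 26)^2)
})

test_that("choose_step takes the argmin and breaks exact ties uniformly", {
  p <- saw_params()
  h0 <- matrix(0, 51, 51)
  # flat field at the centre: all four neighbours tie
  set.seed(20)
  picks <- replicate(10000, paste(choose_step(h0, c(26, 26), p), collapse = ","))
  tab <- table(picks)
  expect_equal(length(tab), 4)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  # unique minimum: deterministic
  h1 <- h0; h1[25, 26] <- -5
  expect_equal(choose_step(h1, c(26, 26), p), c(25, 26))

  # random fields match the exhaustive 4-site scan
  set.seed(21)
  for (rep in 1:200) {
    h <- matrix(runif(51 * 51, 0, 10), 51, 51)
    pos <- c(sample(2:50, 1), sample(2:50, 1))
    nb_i <- pos[1] + c(-1, 1, 0, 0); nb_j <- pos[2] + c(0, 0, -1, 1)
    vals <- h[cbind(nb_i, nb_j)] + potential_u(nb_i, nb_j, p)
    best <- which.min(vals)
    expect_equal(choose_step(h, pos, p), c(nb_i[best], nb_j[best]))
  }
})

test_that("a single iteration composes deposit, decay and movement correctly", {
  p <- saw_params(epsilon = 1e-3)
  st <- list(h = matrix(0, 51, 51), pos = c(26, 26))
  out <- saw_iteration(st, p, u_tie = 0.1)
  expect_equal(out$h[26, 26], 1 - 1e-3) # own deposit, then global decay
  expect_equal(sum(out$h), 1 - 1e-3)    # nothing else touched
  expect_null(out$event)
  expect_equal(sum(abs(out$pos - c(26, 26))), 1) # moved to a 4-neighbour
})

test_that("threshold crossings trigger jumps to the global argmin of h + u + u1", {
  p <- saw_params()
  set.seed(22)
  h <- matrix(runif(51 * 51, 0, 3), 51, 51)
  h[30, 30] <- p$h_c + 1
  out <- saw_iteration(list(h = h, pos = c(30, 30)), p, u_tie = 0.0)
  expect_false(is.null(out$event))
  # oracle: full-lattice scan including this visit's own deposit
  h2 <- h; h2[30, 30] <- h2[30, 30] + 1
  ii <- rep(1:51, times = 51); jj <- rep(1:51, each = 51)
  tot <- as.vector(h2) + potential_u(ii, jj, p) + potential_u1(ii, jj, p)
  k <- which.min(tot)
  expect_equal(out$event$to, c(ii[k], jj[k]))
  expect_equal(out$event$from, c(30, 30))
})

test_that("an unreachable threshold yields no events and a reachable one some", {
  p_inf <- saw_params(h_c = 1e9, burn_in = 500)
  sim <- simulate_saw(2000, p_inf, seed = 23)
  expect_equal(nrow(sim$events), 0)
})

test_that("simulations replay bit-identically from a seed", {
  p <- saw_params(burn_in = 300)
  a <- simulate_saw(400, p, seed = 24)
  b <- simulate_saw(400, p, seed = 24)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$events, b$events)
})

test_that("the optimised engine reproduces the explicit-matrix replay exactly", {
  for (seed in c(31, 32)) {
    p <- saw_params(burn_in = 0, h_c = 3) # low threshold so jumps occur too
    eng <- femwalk:::saw_engine(400, p, variant = "saw", tau = 0L,
                                noise_sd = 0, noise_enabled = FALSE, seed = seed)
    ref <- saw_naive(400, p, variant = "saw", seed = seed)
    expect_equal(cbind(eng$trajectory$x, eng$trajectory$y), ref$traj,
                 ignore_attr = TRUE)
    expect_equal(nrow(eng$events), ref$n_events)
  }
})

test_that("walker stays on the lattice and the field stays bounded", {
  p <- saw_params(L = 21, burn_in = 200, epsilon = 0.01)
  sim <- simulate_saw(2000, p, seed = 25)
  expect_true(all(abs(sim$trajectory$x) <= 10))
  expect_true(all(abs(sim$trajectory$y) <= 10))

  # geometric-series bound on any site: 1/epsilon plus the initial values
  st <- list(h = matrix(runif(21 * 21), 21, 21), pos = c(11, 11))
  p2 <- saw_params(L = 21, epsilon = 0.01, h_c = 1e9)
  for (t in 1:2000) st <- saw_iteration(st, p2)
  expect_lt(max(st$h), 1 / 0.01 + 1)
})

test_that("instant fading with a flat potential gives Brownian scaling", {
  p <- saw_params(L = 151, lambda = 0, epsilon = 0.999, h_c = 1e9, burn_in = 100)
  sims <- lapply(1:5, function(s) simulate_saw(5000, p, seed = 200 + s)$trajectory)
  curves <- lapply(sims, function(tr) msd(tr, max_lag = 400))
  a <- fit_scaling_exponent(average_curves(curves), c(120, 800))$alpha
  expect_gt(a, 0.8); expect_lt(a, 1.2)
})

test_that("microsaccade landings sit in the low-potential region near the axes", {
  # landings follow the global argmin of h + u + u1, so they cluster in the
  # central low-potential region and avoid the lattice diagonals
  sims <- lapply(1:4, function(s) {
    simulate_dsaw(5000, "dr", tau = 10, seed = 300 + s,
                  params = saw_params(h_c = 10, burn_in = 5000))
  })
  ev <- dplyr::bind_rows(lapply(sims, function(s) s$events))
  expect_gt(nrow(ev), 3)
  d_to <- sqrt(ev$to_x^2 + ev$to_y^2)
  expect_lt(median(d_to), 51 / 4) # well inside the lattice
  # axis bias of u1: landing sites lie closer to an axis than the diagonal
  axis_dist <- pmin(abs(ev$to_x), abs(ev$to_y))
  expect_lt(median(axis_dist), median(d_to) / sqrt(2))
})

test_that("the pre-deposit trigger convention never fires at the default threshold", {
  # the activation the walker encounters before depositing equilibrates
  # below h_c = 7.9, which is why the threshold test includes the deposit
  p_pre <- saw_params(trigger = "pre-deposit", burn_in = 5000)
  sim <- simulate_saw(10000, p_pre, seed = 26)
  expect_equal(nrow(sim$events), 0)
  p_post <- saw_params(burn_in = 5000)
  n_post <- sum(vapply(1:4, function(s) {
    nrow(simulate_saw(10000, p_post, seed = 26 + s)$events)
  }, integer(1)))
  expect_gt(n_post, 0)
})
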