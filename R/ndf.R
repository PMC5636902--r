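#' Parameters of the non-linear delayed feedback (NDF) drift model
#'
#' The NDF model describes one movement component of fixational drift as a
#' first-order autoregressive map of the activity `w` of excitatory burst
#' neurons with a tanh-saturated, negative feedback delayed by `tau` samples:
#' \deqn{w_{i+1} = (1-\gamma) w_i + \xi_i - \lambda \tanh(\varepsilon\,
#'   w_{i-\tau}), \qquad x_{i+1} = x_i + w_{i+1} + \eta_i,}
#' with i.i.d. Gaussian noises \eqn{\xi \sim N(0, \sigma^2)} (burst baseline)
#' and \eqn{\eta \sim N(0, \rho^2)} (tonic-unit / position noise). Defaults
#' are the calibrated set `gamma = 0.25`, `lambda = 0.15`, `epsilon = 1.1`,
#' `sigma = 0.075`, `rho = 0.35`; the delay is 35 samples (70 ms) for the
#' horizontal and 20 samples (40 ms) for the vertical component.
#'
#' @param gamma Leak rate of the activity map, in `[0, 1]`.
#' @param lambda Feedback gain (>= 0).
#' @param epsilon Feedback steepness (> 0).
#' @param sigma SD of the burst noise `xi`.
#' @param rho SD of the position noise `eta`.
#' @param tau Feedback delay in samples (non-negative integer).
#' @param burn_in Discarded initial samples (default 2000, far longer than
#'   any default delay, so start-up transients from the zero history die out).
#' @return A list of class `ndf_params`.
#' @export
ndf_params <- function(gamma = 0.25, lambda = 0.15, epsilon = 1.1,
                       sigma = 0.075, rho = 0.35, tau = 35L, burn_in = 2000L) {
  stopifnot(gamma >= 0, gamma <= 1, lambda >= 0, epsilon > 0,
            sigma >= 0, rho >= 0, tau >= 0, tau == as.integer(tau), burn_in >= 0)
  structure(list(gamma = gamma, lambda = lambda, epsilon = epsilon,
                 sigma = sigma, rho = rho, tau = as.integer(tau),
                 burn_in = as.integer(burn_in)),
            class = "ndf_params")
}

#' Simulate one component of the NDF drift model
#'
#' Iterates the delayed autoregressive map (see [ndf_params()]) from a zero
#' activity history (`w_j = 0` for `j <= 0`) and position 0, discards the
#' burn-in, and returns the remaining `n_steps` positions at a 2 ms sample
#' interval. The same seed reproduces the trajectory exactly.
#'
#' @param n_steps Number of recorded samples (>= 1).
#' @param params An [ndf_params()] object.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param dt Sample interval in seconds attached to the output.
#' @return A tibble with columns `time` and `x` (model units).
#' @export
simulate_ndf <- function(n_steps, params = ndf_params(), seed = NULL, dt = 0.002) {
  stopifnot(n_steps >= 1, inherits(params, "ndf_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  total <- p$burn_in + n_steps
  xi <- rnorm(total, 0, p$sigma)
  eta <- rnorm(total, 0, p$rho)
  w <- numeric(total + 1L)
  x <- numeric(total + 1L)
  tau <- p$tau
  for (i in seq_len(total)) {
    wd <- if (i - tau >= 1L) w[[i - tau]] else 0
    w[[i + 1L]] <- (1 - p$gamma) * w[[i]] + xi[[i]] - p$lambda * tanh(p$epsilon * wd)
    x[[i + 1L]] <- x[[i]] + w[[i + 1L]] + eta[[i]]
  }
  keep <- (p$burn_in + 2L):(total + 1L)
  tibble(time = (seq_len(n_steps) - 1) * dt, x = x[keep])
}

#' Simulate a two-component NDF trajectory
#'
#' Runs two independent one-component simulations (typically with different
#' delays for the horizontal and vertical control loops) on separate
#' sub-streams derived from `seed`, and combines them into a 2-D trajectory.
#' By construction the components are statistically independent.
#'
#' @inheritParams simulate_ndf
#' @param params_hor,params_ver [ndf_params()] for the horizontal and
#'   vertical component (defaults: delays 35 and 20 samples).
#' @return A trajectory tibble with columns `time`, `x`, `y` (model units).
#' @export
simulate_ndf_2d <- function(n_steps, params_hor = ndf_params(tau = 35L),
                            params_ver = ndf_params(tau = 20L),
                            seed = NULL, dt = 0.002) {
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  hor <- simulate_ndf(n_steps, params_hor, seed = trial_seed(seed, 1L), dt = dt)
  ver <- simulate_ndf(n_steps, params_ver, seed = trial_seed(seed, 2L), dt = dt)
  tibble(time = hor$time, x = hor$x, y = ver$x)
}
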