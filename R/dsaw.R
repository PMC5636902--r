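#' Apply rounded Gaussian read-out noise to a lattice position
#'
#' Adds `round(delta)` with \eqn{\delta \sim N(0, \mathrm{noise\_sd}^2)} to
#' each coordinate and clamps the result to the lattice. With the default
#' `noise_sd = 0.3` a coordinate is displaced with probability
#' \eqn{2(1 - \Phi(0.5/0.3)) \approx 9.6\%}. In the delayed SAW variants this
#' noise prevents the walker from getting trapped in short revisited trails,
#' and is applied in all variants so they stay comparable.
#'
#' @param pos Integer length-2 position `c(i, j)`.
#' @param noise_sd Standard deviation of the Gaussian offset (>= 0).
#' @param L Lattice side length used for clamping.
#' @param delta Optional length-2 Gaussian draw (defaults to
#'   `rnorm(2, 0, noise_sd)`); exposing it makes the operation replayable.
#' @return Integer length-2 position within `[1, L]^2`.
#' @export
noisy_position <- function(pos, noise_sd, L, delta = NULL) {
  stopifnot(length(pos) == 2, noise_sd >= 0, L >= 1)
  if (is.null(delta)) delta <- rnorm(2, 0, noise_sd)
  out <- as.integer(pos) + as.integer(round(delta))
  pmin(pmax(out, 1L), as.integer(L))
}

#' Simulate a time-delayed self-avoiding walk (D-SAW)
#'
#' Runs one of the four delayed variants of the fading SAW, which apply a
#' delay of `tau` iterations (2 ms each) to different parts of the update:
#'
#' * `"ds"` — delayed activation **state**: the step readout happens at the
#'   current position but evaluates the activation field as it was `tau`
#'   iterations earlier.
#' * `"dr"` — delayed **readout** position: the current field is read out
#'   around the delayed position `x(t - tau)`; the winning neighbour defines
#'   a relative step that is applied at the walker's true position.
#' * `"da"` — delayed **activation-setting** position: the unit deposit goes
#'   to the delayed position while the readout stays current.
#' * `"dar"` — both `"da"` and `"dr"` (one shared noisy delayed position is
#'   used for deposit and readout).
#'
#' Rounded Gaussian read-out noise ([noisy_position()]) blurs each variant's
#' delayed quantity: the delayed read-out position (`dr`, `dar`), the
#' delayed deposit position (`da`, `dar`), and the deposits of the
#' delayed-state variant (`ds`), so the four variants remain comparable.
#' Microsaccade triggering always uses the walker's current position (an
#' efference-copy style, delay-free position signal); the activation value
#' tested is the field the variant reads out (the delayed state for `ds`,
#' the current state otherwise), which keeps the delayed-state and
#' delayed-setting variants symmetric. During the first `tau` burn-in
#' iterations the delay buffers are not yet primed: variants that read out a
#' delayed quantity (`dr`, `dar`, `ds`) step isotropically at random, and
#' variants that deposit at a delayed position (`da`, `dar`) skip the
#' deposit and pause the global decay. With `tau = 0` and noise disabled
#' every variant reproduces [simulate_saw()] bit for bit under the same
#' seed.
#'
#' @inheritParams simulate_saw
#' @param variant One of `"ds"`, `"dr"`, `"da"`, `"dar"`.
#' @param tau Delay in iterations (>= 0); delays of 10--18 iterations
#'   (20--36 ms) are the physiologically interesting range.
#' @param params A [saw_params()] object. Defaults to [saw_params()] with
#'   `h_c = 17.5` for the `dr`/`dar` variants (the delayed readout makes
#'   high-activation visits much more frequent, so the trigger threshold is
#'   raised to keep the microsaccade rate comparable) and `h_c = 7.9`
#'   otherwise.
#' @param noise_sd SD of the rounded Gaussian read-out noise (default 0.3).
#' @param noise_enabled Set `FALSE` to disable the read-out noise.
#' @return A `saw_sim` object (see [simulate_saw()]).
#' @export
simulate_dsaw <- function(n_steps, variant = c("ds", "dr", "da", "dar"),
                          tau = 15L, params = NULL, noise_sd = 0.3,
                          noise_enabled = TRUE, seed = NULL, dt = 0.002) {
  variant <- match.arg(variant)
  if (is.null(params)) {
    params <- if (variant %in% c("dr", "dar")) saw_params(h_c = 17.5) else saw_params()
  }
  saw_engine(n_steps, params, variant = variant, tau = tau,
             noise_sd = noise_sd, noise_enabled = noise_enabled,
             seed = seed, dt = dt)
}
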