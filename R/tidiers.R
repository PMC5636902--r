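#' Tidy a scaling-exponent fit
#'
#' @param x A `fem_scaling` object from [fit_scaling_exponent()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`intercept`, `alpha`).
#' @exportS3Method generics::tidy
tidy.fem_scaling <- function(x, ...) {
  tibble(
    term = c("intercept", "alpha"),
    estimate = c(x$intercept, x$alpha),
    std.error = c(NA_real_, x$std_error)
  )
}

#' One-row summary of a scaling-exponent fit
#'
#' @inheritParams tidy.fem_scaling
#' @return A one-row tibble with `alpha`, `std.error`, `r.squared`, `sigma`,
#'   `n_lags`, and the fit window.
#' @exportS3Method generics::glance
glance.fem_scaling <- function(x, ...) {
  tibble(
    alpha = x$alpha, std.error = x$std_error, r.squared = x$r_squared,
    sigma = x$sigma, n_lags = x$n_lags,
    range_lo_ms = x$range_ms[[1]], range_hi_ms = x$range_ms[[2]]
  )
}

#' Tidy a single-run SAW simulation into its trajectory
#'
#' @param x A `saw_sim` object.
#' @param ... Unused.
#' @return The trajectory tibble (`time`, `x`, `y`).
#' @exportS3Method generics::tidy
tidy.saw_sim <- function(x, ...) x$trajectory

#' One-row summary of a single-run SAW simulation
#'
#' @inheritParams tidy.saw_sim
#' @return A one-row tibble with the variant, delay, step count and
#'   microsaccade count/rate.
#' @exportS3Method generics::glance
glance.saw_sim <- function(x, ...) {
  n <- nrow(x$trajectory)
  tibble(
    variant = x$variant, tau = x$tau, n_steps = n, n_events = nrow(x$events),
    event_rate_hz = nrow(x$events) / (n * x$dt)
  )
}

#' Tidy a multi-trial simulation into its long trial table
#'
#' @param x A `fem_sim` object from [simulate_fem()].
#' @param ... Unused.
#' @return The long tibble of trials (`trial`, `time`, `x`, `y`).
#' @exportS3Method generics::tidy
tidy.fem_sim <- function(x, ...) x$trials

#' One-row summary of a multi-trial simulation
#'
#' @inheritParams tidy.fem_sim
#' @return A one-row tibble with the model, trial/step counts and the mean
#'   microsaccade rate.
#' @exportS3Method generics::glance
glance.fem_sim <- function(x, ...) {
  tibble(
    model = x$model, n_trials = x$n_trials, n_steps = x$n_steps,
    n_events = nrow(x$events),
    event_rate_hz = nrow(x$events) / (x$n_trials * x$n_steps * x$dt)
  )
}
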