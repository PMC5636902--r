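#' Time-averaged mean squared displacement
#'
#' Computes the time-averaged MSD of a single trajectory,
#' \deqn{\mathrm{MSD}(l) = \frac{1}{N-l} \sum_{i=1}^{N-l} (x_{i+l} - x_i)^2,}
#' where the square is the Euclidean norm over both components
#' (`component = "both"`) or a single component. Time averaging over one
#' long trajectory replaces the ensemble average, which is appropriate when
#' only a limited number of trials is available; curves are typically then
#' averaged across trials with [average_curves()].
#'
#' @param traj Trajectory tibble with columns `time`, `x`, `y`.
#' @param max_lag Largest lag in samples (must be `< N`). Default covers
#'   1200 ms at the trajectory's sample interval (capped at `N - 2`).
#' @param component `"both"` (2-D, default), `"x"` or `"y"`.
#' @return A tibble with columns `lag` (samples, `1:max_lag`), `lag_ms`, and
#'   `value` (squared position units).
#' @examples
#' tr <- new_trajectory(0.1 * (1:100), rep(0, 100))
#' msd(tr, max_lag = 5) # ballistic: value = (0.1 * lag)^2
#' @export
msd <- function(traj, max_lag = NULL, component = c("both", "x", "y")) {
  component <- match.arg(component)
  tr <- check_trajectory(traj)
  n <- tr$n
  if (is.null(max_lag)) max_lag <- min(n - 2L, ceiling(1.2 / tr$dt))
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) abort("`max_lag` must be smaller than the trajectory length.")
  if (max_lag < 1) abort("`max_lag` must be at least 1.")
  lags <- seq_len(max_lag)
  val <- vapply(lags, function(l) {
    sq <- 0
    if (component != "y") sq <- sq + (tr$x[(1 + l):n] - tr$x[1:(n - l)])^2
    if (component != "x") sq <- sq + (tr$y[(1 + l):n] - tr$y[1:(n - l)])^2
    mean(sq)
  }, numeric(1))
  tibble(lag = lags, lag_ms = lags * tr$dt * 1000, value = val)
}

#' Normalised displacement autocorrelation function
#'
#' Correlates displacement vectors over a fixed interval of `k` samples
#' separated by lag `l`:
#' \deqn{\overline{\mathrm{DACF}}(l) = \frac{1}{N-l-k} \sum_{i=1}^{N-l-k}
#'   \frac{(x_{i+l+k}-x_{i+l}) \cdot (x_{i+k}-x_i)}{k^2},}
#' returned normalised as
#' \eqn{\mathrm{DACF}(l) = \overline{\mathrm{DACF}}(l) /
#' \overline{\mathrm{DACF}}(0)} so the curve equals 1 at zero lag. Positive
#' lobes after the initial decay indicate oscillatory, delay-like dynamics;
#' a purely negative rebound indicates plain antipersistence.
#'
#' @inheritParams msd
#' @param k Displacement interval in samples (default 25, i.e. 50 ms at
#'   500 Hz).
#' @param max_lag Largest lag in samples (`max_lag + k < N`). Default covers
#'   600 ms at the trajectory's sample interval.
#' @return A tibble with columns `lag` (`0:max_lag`), `lag_ms`, `value`
#'   (unitless, `value[lag == 0] == 1`).
#' @export
dacf <- function(traj, k = 25L, max_lag = NULL, component = c("both", "x", "y")) {
  component <- match.arg(component)
  tr <- check_trajectory(traj)
  n <- tr$n
  k <- as.integer(k)
  if (k < 1) abort("`k` must be at least 1.")
  if (is.null(max_lag)) max_lag <- min(n - k - 2L, ceiling(0.6 / tr$dt))
  max_lag <- as.integer(max_lag)
  if (max_lag + k >= n) abort("trajectory too short: need `max_lag + k < N`.")
  dx <- tr$x[(1 + k):n] - tr$x[1:(n - k)]
  dy <- tr$y[(1 + k):n] - tr$y[1:(n - k)]
  m <- n - k
  raw <- vapply(0:max_lag, function(l) {
    prod <- 0
    if (component != "y") prod <- prod + dx[(1 + l):m] * dx[1:(m - l)]
    if (component != "x") prod <- prod + dy[(1 + l):m] * dy[1:(m - l)]
    mean(prod) / k^2
  }, numeric(1))
  if (!is.finite(raw[[1]]) || raw[[1]] <= 0) {
    abort("DACF(0) must be positive; the trajectory appears constant.")
  }
  tibble(lag = 0:max_lag, lag_ms = (0:max_lag) * tr$dt * 1000,
         value = raw / raw[[1]])
}

#' Average correlation curves across trials
#'
#' Pointwise arithmetic mean of per-trial curves sharing an identical lag
#' grid, with the per-lag standard deviation across trials (the error bars of
#' trial-averaged MSD/DACF plots). DACF curves are averaged after their
#' per-trial normalisation.
#'
#' @param curves A list of curve tibbles (each with columns `lag`, `lag_ms`,
#'   `value`), or a single long tibble with a `trial` column.
#' @return A tibble with columns `lag`, `lag_ms`, `value` (mean), `sd`, `n`.
#' @export
average_curves <- function(curves) {
  if (is.data.frame(curves)) {
    if (!"trial" %in% names(curves)) return(mutate(curves, sd = 0, n = 1L))
    curves <- split(curves[setdiff(names(curves), "trial")], curves$trial)
  }
  stopifnot(length(curves) >= 1)
  ref <- curves[[1]]$lag
  for (cv in curves) {
    if (length(cv$lag) != length(ref) || any(cv$lag != ref)) {
      abort("all curves must share an identical lag grid.")
    }
  }
  vals <- vapply(curves, function(cv) cv$value, numeric(length(ref)))
  vals <- matrix(vals, nrow = length(ref))
  s <- apply(vals, 1, stats::sd)
  s[is.na(s)] <- 0 # a single curve has no across-trial spread
  tibble(
    lag = ref,
    lag_ms = curves[[1]]$lag_ms,
    value = rowMeans(vals),
    sd = s,
    n = length(curves)
  )
}

#' Fit a power-law scaling exponent to an MSD curve
#'
#' Ordinary least-squares fit of `log10(MSD)` against `log10(lag time)` over
#' all integer lags whose lag time falls inside the window `range_ms`
#' (inclusive endpoints). The slope is the scaling exponent \eqn{\alpha} of
#' \eqn{\mathrm{MSD}(\tau) \propto \tau^\alpha}: \eqn{\alpha = 1} is
#' uncorrelated (Brownian) motion, \eqn{\alpha > 1} persistence,
#' \eqn{\alpha < 1} antipersistence. Conventional windows at 500 Hz are
#' 2--12 ms (short scale) and 120--1200 ms (long scale).
#'
#' @param curve MSD curve tibble with columns `lag_ms` and `value` (e.g. from
#'   [msd()] or [average_curves()]).
#' @param range_ms Numeric length-2 fit window in ms, endpoints inclusive.
#' @return An object of class `fem_scaling` with elements `alpha`,
#'   `intercept`, `std_error`, `r_squared`, `sigma`, `n_lags`, `range_ms`,
#'   and the windowed `data`. Supports [tidy()], [glance()] and `print()`.
#' @examples
#' curve <- msd(new_trajectory(0.1 * (1:200), rep(0, 200)), max_lag = 50)
#' fit_scaling_exponent(curve, range_ms = c(2, 12)) # alpha = 2 (ballistic)
#' @export
fit_scaling_exponent <- function(curve, range_ms) {
  stopifnot(all(c("lag_ms", "value") %in% names(curve)),
            length(range_ms) == 2, range_ms[[1]] < range_ms[[2]])
  eps <- 1e-9 * max(abs(range_ms)) # inclusive endpoints despite fp lag times
  win <- curve[curve$lag_ms >= range_ms[[1]] - eps &
                 curve$lag_ms <= range_ms[[2]] + eps, ]
  if (nrow(win) < 3) abort("fewer than 3 lags fall inside the fit window.")
  if (any(win$value <= 0)) abort("MSD values must be positive inside the fit window.")
  fit <- lm(log10(value) ~ log10(lag_ms / 1000), data = win)
  sm <- suppressWarnings(summary(fit)) # exact power laws fit perfectly
  structure(
    list(
      alpha = unname(coef(fit)[[2]]),
      intercept = unname(coef(fit)[[1]]),
      std_error = unname(sm$coefficients[2, 2]),
      r_squared = sm$r.squared,
      sigma = sm$sigma,
      n_lags = nrow(win),
      range_ms = as.double(range_ms),
      data = win
    ),
    class = "fem_scaling"
  )
}

#' @export
print.fem_scaling <- function(x, ...) {
  cat(sprintf(
    "Scaling-exponent fit over %.0f-%.0f ms (%d lags)\n  alpha = %.4f (SE %.4f), R^2 = %.4f\n",
    x$range_ms[[1]], x$range_ms[[2]], x$n_lags, x$alpha, x$std_error, x$r_squared
  ))
  invisible(x)
}

#' Oscillation metrics of a DACF curve
#'
#' Locates the first positive local maximum of the DACF after its initial
#' decay through zero. The lag of that maximum is read as the oscillation
#' period `T` of the underlying movement, and inverting the delay--period
#' band \eqn{2\tau < T < 4\tau} of time-delayed feedback systems yields
#' bounds `(T/4, T/2)` on the feedback delay. Absence of a zero crossing or
#' of a positive local maximum is a first-class "no oscillation" outcome
#' (not an error), since model discrimination rests on it.
#'
#' @param curve DACF curve tibble with columns `lag_ms` and `value`, spanning
#'   at least 400 ms of lag.
#' @param min_peak Minimum height a local maximum must exceed to count as an
#'   oscillation (default 0: any positive strict local maximum). A small
#'   positive floor (e.g. 0.05) makes the call robust to estimator noise on
#'   trial-averaged curves.
#' @param presmooth If `TRUE`, apply a 3-point moving average before peak
#'   search (off by default; averaged curves are usually smooth enough).
#' @return A one-row tibble: `detected`, `first_max_lag_ms`,
#'   `first_max_value`, `period_ms`, `delay_lower_ms`, `delay_upper_ms`
#'   (the latter five `NA` when no oscillation is detected).
#' @export
oscillation_metrics <- function(curve, min_peak = 0, presmooth = FALSE) {
  stopifnot(all(c("lag_ms", "value") %in% names(curve)))
  curve <- curve[order(curve$lag_ms), ]
  if (max(curve$lag_ms) < 400) {
    abort("DACF curve must span at least 400 ms of lag for oscillation metrics.")
  }
  v <- curve$value
  if (presmooth && length(v) >= 3) {
    v <- c(v[[1]], (v[-c(1, 2)] + v[-c(1, length(v))] + v[-c(length(v) - 1, length(v))]) / 3,
           v[[length(v)]])
  }
  none <- tibble(detected = FALSE, first_max_lag_ms = NA_real_,
                 first_max_value = NA_real_, period_ms = NA_real_,
                 delay_lower_ms = NA_real_, delay_upper_ms = NA_real_)
  cross <- which(v < 0)
  if (length(cross) == 0) return(none)
  i0 <- cross[[1]]
  if (i0 + 1 > length(v) - 1) return(none)
  for (i in (i0 + 1):(length(v) - 1)) {
    if (v[[i]] > v[[i - 1]] && v[[i]] > v[[i + 1]] && v[[i]] > min_peak && v[[i]] > 0) {
      period <- curve$lag_ms[[i]]
      b <- delay_bounds(period)
      return(tibble(detected = TRUE, first_max_lag_ms = period,
                    first_max_value = v[[i]], period_ms = period,
                    delay_lower_ms = b[["lower"]], delay_upper_ms = b[["upper"]]))
    }
  }
  none
}

#' Feedback-delay bounds implied by an oscillation period
#'
#' Time-delayed feedback systems oscillate with a period between two and
#' four times the delay, \eqn{2\tau < T < 4\tau}. Inverting this band for an
#' observed period `T` brackets the delay as \eqn{T/4 < \tau < T/2}.
#'
#' @param period_ms Oscillation period(s) in ms.
#' @return A named numeric vector (or matrix for vector input) with entries
#'   `lower` (`T/4`) and `upper` (`T/2`) in ms.
#' @examples
#' delay_bounds(100) # 25-50 ms
#' delay_bounds(200) # 50-100 ms
#' @export
delay_bounds <- function(period_ms) {
  stopifnot(all(period_ms > 0))
  if (length(period_ms) == 1) {
    c(lower = period_ms / 4, upper = period_ms / 2)
  } else {
    cbind(lower = period_ms / 4, upper = period_ms / 2)
  }
}
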