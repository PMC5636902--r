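#' Five-point velocity estimate of a trajectory
#'
#' Estimates instantaneous velocity with a weighted moving average over five
#' successive samples,
#' \deqn{v_i = \frac{x_{i+2} + x_{i+1} - x_{i-1} - x_{i-2}}{6\,\Delta t}}
#' for interior samples \eqn{i = 3 \dots N-2}, and the symmetric central
#' difference \eqn{v_i = (x_{i+1} - x_{i-1}) / (2\Delta t)} at the two
#' boundary samples \eqn{i \in \{2, N-1\}}. The endpoints \eqn{i = 1, N}
#' carry no estimate, so the result has \eqn{N - 2} rows. The five-point
#' filter suppresses sample-to-sample measurement noise while reproducing
#' linear motion exactly.
#'
#' @param traj A trajectory tibble with columns `time`, `x`, `y` (N >= 5
#'   uniformly sampled rows).
#' @return A tibble with columns `sample` (original index, `2:(N-1)`),
#'   `time`, `vx`, `vy` in position units per second.
#' @examples
#' tr <- new_trajectory(1:20, rep(0, 20))
#' estimate_velocity(tr) # vx = 500 units/s throughout at dt = 0.002
#' @export
estimate_velocity <- function(traj) {
  tr <- check_trajectory(traj)
  n <- tr$n; dt <- tr$dt
  v1 <- function(x) {
    i <- 3:(n - 2)
    mid <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
    lo <- (x[3] - x[1]) / (2 * dt)
    hi <- (x[n] - x[n - 2]) / (2 * dt)
    c(lo, mid, hi)
  }
  tibble(
    sample = 2:(n - 1),
    time = tr$time[2:(n - 1)],
    vx = v1(tr$x),
    vy = v1(tr$y)
  )
}

#' Integrate a velocity series back into a trajectory
#'
#' Cumulative summation of velocity samples,
#' \eqn{x^s_i = x_1 + \Delta t \sum_{j=2}^{i-1} v_j}, with the convention
#' \eqn{x^s_1 = x^s_2 = x_1} (empty sum). The output has two samples more
#' than the velocity series. Together with [estimate_velocity()] this defines
#' the smoothing operator; integrating a velocity series with episodes
#' removed yields a correspondingly shorter trajectory.
#'
#' @param vel A velocity tibble with columns `vx`, `vy` (as returned by
#'   [estimate_velocity()], possibly with rows deleted).
#' @param x1 Numeric length-2 start position `c(x, y)`.
#' @param dt Sample interval in seconds.
#' @param t0 Time of the first output sample (default 0).
#' @return A trajectory tibble with `nrow(vel) + 2` rows.
#' @export
integrate_velocity <- function(vel, x1, dt, t0 = 0) {
  stopifnot(is.data.frame(vel), all(c("vx", "vy") %in% names(vel)),
            length(x1) == 2, dt > 0)
  if (anyNA(vel$vx) || anyNA(vel$vy)) abort("velocity series contains missing values.")
  xs <- c(x1[[1]], x1[[1]], x1[[1]] + dt * cumsum(vel$vx))
  ys <- c(x1[[2]], x1[[2]], x1[[2]] + dt * cumsum(vel$vy))
  new_trajectory(xs, ys, dt = dt, t0 = t0)
}

#' Smooth a trajectory by velocity estimation and re-integration
#'
#' Applies [estimate_velocity()] followed by [integrate_velocity()] from the
#' first sample. Exact for trajectories that are (piecewise) linear in time;
#' on noisy recordings it acts as a mild low-pass filter. The output keeps
#' the original length.
#'
#' @inheritParams estimate_velocity
#' @return A trajectory tibble of the same length as `traj`.
#' @export
smooth_trajectory <- function(traj) {
  tr <- check_trajectory(traj)
  vel <- estimate_velocity(traj)
  integrate_velocity(vel, c(tr$x[[1]], tr$y[[1]]), dt = tr$dt, t0 = tr$time[[1]])
}

#' Smooth every trial of a long trial table
#'
#' Grouped wrapper around [smooth_trajectory()]: smooths each trial (and eye,
#' if present) independently and returns the same long format.
#'
#' @param trials Long tibble with columns `time`, `x`, `y` and optionally
#'   `trial`, `eye`.
#' @return A tibble of the same shape with smoothed positions.
#' @export
smooth_trials <- function(trials) {
  gcols <- intersect(c("trial", "eye"), names(trials))
  if (length(gcols) == 0) return(smooth_trajectory(trials))
  trials |>
    group_by(dplyr::across(dplyr::all_of(gcols))) |>
    dplyr::group_modify(~ smooth_trajectory(.x)) |>
    ungroup()
}

# Median-based scale of the elliptical threshold: sigma^2 per component is
# median(v^2) - median(v)^2, a robust surrogate for the variance that keeps
# the threshold insensitive to the large velocities of the microsaccades
# themselves. Can be non-positive on degenerate input.
ms_sigma <- function(v) {
  s2 <- stats::median(v^2) - stats::median(v)^2
  if (!is.finite(s2) || s2 <= 0) {
    abort("degenerate threshold: median-based velocity variance is not positive.",
          class = "femwalk_degenerate_threshold")
  }
  sqrt(s2)
}

#' Detect microsaccades in one eye with an elliptical velocity threshold
#'
#' Flags samples whose velocity falls outside the ellipse
#' \eqn{(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1} with per-component thresholds
#' \eqn{\eta = \lambda\,\sigma} where \eqn{\sigma} is a median-based scale of
#' the velocity distribution (see Details). A microsaccade is a maximal run
#' of at least `min_samples` consecutive suprathreshold velocity samples
#' (default 3, i.e. 6 ms at 500 Hz). Runs separated by one or more
#' subthreshold samples are distinct episodes.
#'
#' @details The per-component scale is
#'   \eqn{\sigma^2 = \mathrm{median}(v^2) - \mathrm{median}(v)^2}, which makes
#'   the threshold robust against the very saccadic velocities it is meant to
#'   find. A non-positive value (e.g. constant velocity) raises a
#'   `femwalk_degenerate_threshold` error. Detection is invariant under adding
#'   a constant offset to all positions.
#'
#' @param x Either a velocity tibble (columns `sample`, `vx`, `vy`) from
#'   [estimate_velocity()], or a trajectory tibble (`time`, `x`, `y`), in
#'   which case velocities are estimated first.
#' @param lambda Threshold multiplier (default 5).
#' @param min_samples Minimum run length in velocity samples (default 3).
#' @return A tibble of episodes with columns `onset`, `end` (velocity sample
#'   indices into the original trajectory), and `n_samples`; zero rows when
#'   nothing is detected.
#' @export
detect_microsaccades <- function(x, lambda = 5, min_samples = 3L) {
  stopifnot(lambda > 0, min_samples >= 1)
  vel <- if (all(c("vx", "vy") %in% names(x))) x else estimate_velocity(x)
  eta_x <- lambda * ms_sigma(vel$vx)
  eta_y <- lambda * ms_sigma(vel$vy)
  above <- (vel$vx / eta_x)^2 + (vel$vy / eta_y)^2 > 1
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_samples
  idx <- if ("sample" %in% names(vel)) vel$sample else seq_len(nrow(vel))
  tibble(
    onset = idx[starts[keep]],
    end = idx[ends[keep]],
    n_samples = runs$lengths[keep]
  )
}

#' Pair monocular episodes into binocular microsaccades
#'
#' Keeps a left/right pair of monocular episodes when they overlap by at
#' least one velocity sample, expressed by the strict criterion
#' `r_end > l_onset` and `r_onset < l_end` (episodes that merely touch at a
#' shared endpoint are rejected). Each overlapping pair yields one binocular
#' episode spanning the union of the two intervals; unmatched monocular
#' episodes are dropped. The operation is symmetric in its arguments up to
#' episode labelling.
#'
#' @param left,right Episode tibbles with columns `onset`, `end` (sorted,
#'   disjoint within one eye), as returned by [detect_microsaccades()].
#' @return A tibble of binocular episodes with columns `onset`, `end`,
#'   `n_samples`.
#' @export
pair_binocular <- function(left, right) {
  stopifnot(all(c("onset", "end") %in% names(left)),
            all(c("onset", "end") %in% names(right)))
  if (nrow(left) == 0 || nrow(right) == 0) {
    return(tibble(onset = integer(), end = integer(), n_samples = integer()))
  }
  pairs <- tidyr::crossing(
    tibble(l_onset = left$onset, l_end = left$end),
    tibble(r_onset = right$onset, r_end = right$end)
  ) |>
    filter(.data$r_end > .data$l_onset, .data$r_onset < .data$l_end) |>
    mutate(onset = pmin(.data$l_onset, .data$r_onset),
           end = pmax(.data$l_end, .data$r_end)) |>
    arrange(.data$onset, .data$end)
  tibble(
    onset = pairs$onset,
    end = pairs$end,
    n_samples = pairs$end - pairs$onset + 1L
  )
}

#' Remove microsaccade episodes and re-integrate the trajectory
#'
#' Deletes the velocity samples covered by the episodes from the five-point
#' velocity series of `traj`, concatenates the remaining samples in order,
#' and re-integrates from the first position. With an empty episode list the
#' result equals [smooth_trajectory()]; removing `m` velocity samples
#' shortens the trajectory by `m`.
#'
#' @inheritParams estimate_velocity
#' @param episodes Episode tibble with columns `onset`, `end` holding
#'   velocity sample indices of `traj` (i.e. within `2:(N-1)`).
#' @return A trajectory tibble of length `N - m`.
#' @export
remove_microsaccades <- function(traj, episodes) {
  tr <- check_trajectory(traj)
  vel <- estimate_velocity(traj)
  if (nrow(episodes) > 0) {
    if (any(episodes$onset < 2) || any(episodes$end > tr$n - 1) ||
        any(episodes$end < episodes$onset)) {
      abort("episode indices must lie within the velocity index range 2..N-1.")
    }
    drop <- unique(unlist(Map(seq.int, episodes$onset, episodes$end)))
    vel <- vel[!(vel$sample %in% drop), ]
  }
  integrate_velocity(vel, c(tr$x[[1]], tr$y[[1]]), dt = tr$dt, t0 = tr$time[[1]])
}

#' Binocular microsaccade detection across trials
#'
#' For each trial of a long binocular trial table (columns `trial`, `eye`,
#' `time`, `x`, `y`, with eyes labelled `"left"` and `"right"`), estimates
#' velocities per eye, detects monocular episodes at the elliptical threshold
#' and pairs them with the binocular overlap criterion.
#'
#' @param trials Long binocular trial tibble.
#' @inheritParams detect_microsaccades
#' @return A tibble with columns `trial`, `onset`, `end`, `n_samples`.
#' @export
detect_binocular <- function(trials, lambda = 5, min_samples = 3L) {
  stopifnot(all(c("trial", "eye") %in% names(trials)))
  eyes <- unique(trials$eye)
  if (!all(c("left", "right") %in% eyes)) {
    abort('`trials` must contain eyes labelled "left" and "right".')
  }
  purrr::map_dfr(unique(trials$trial), function(tr) {
    one <- trials[trials$trial == tr, ]
    det <- function(which_eye) {
      detect_microsaccades(one[one$eye == which_eye, c("time", "x", "y")],
                           lambda = lambda, min_samples = min_samples)
    }
    out <- pair_binocular(det("left"), det("right"))
    if (nrow(out) > 0) dplyr::bind_cols(tibble(trial = tr), out)
    else tibble(trial = integer(), onset = integer(), end = integer(),
                n_samples = integer())
  })
}
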