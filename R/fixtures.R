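#' Generate synthetic binocular fixation trials with known microsaccades
#'
#' Synthesises video-eye-tracker-like binocular recordings for end-to-end
#' testing of the preprocessing and correlation stack: correlated drift
#' (two-component NDF simulation, or Brownian motion), injected ballistic
#' microsaccades with a raised-cosine velocity profile, and white
#' measurement noise per eye. Both eyes share the drift and the
#' microsaccades (the right eye's event onsets are jittered by at most
#' `binocular_jitter` samples); measurement noise is independent between
#' eyes. Injected events are gaze-correcting: each one moves predominantly
#' along the horizontal or vertical axis, directed against the accumulated
#' gaze offset, mimicking the error-correcting role of real microsaccades
#' (and giving intact recordings a lower long-range MSD exponent than
#' event-free drift). The ground-truth episode list is returned alongside
#' the trials.
#'
#' Defaults emulate a typical fixation experiment: 30 trials of 20 s at
#' 500 Hz, microsaccades of about 0.5 degree amplitude and 24 ms duration
#' occurring 1-2 times per second with a 100 ms refractory period, drift
#' with a positional SD of about 0.1 degree, and 0.01 degree instrument
#' noise.
#'
#' @param n_trials Number of trials (default 30).
#' @param n_samples Samples per trial (default 10000 = 20 s at 500 Hz).
#' @param dt Sample interval in seconds (default 0.002).
#' @param drift `"ndf"` (default) or `"brownian"` drift source.
#' @param ms_rate Mean microsaccade rate per second (default 1.5; 0 disables
#'   injection). A 100 ms refractory gap is enforced between events.
#' @param ms_amplitude_deg Mean amplitude in degrees (default 0.5); per-event
#'   amplitudes are Gaussian with SD `ms_amplitude_sd`, truncated at 0.1.
#' @param ms_amplitude_sd SD of the amplitude distribution (default 0.1).
#' @param ms_duration_ms Event duration in ms (default 24, i.e. 12 samples;
#'   must be at least 6 ms so events span >= 3 velocity samples and are
#'   detectable by construction).
#' @param noise_sd_deg Measurement noise SD in degrees (default 0.01).
#' @param drift_sd_deg Target positional SD of the drift in degrees
#'   (default 0.1); used when `degree_scale` is `NULL`.
#' @param degree_scale Fixed drift-to-degree multiplier; `NULL` (default)
#'   rescales each trial's drift to `drift_sd_deg`.
#' @param binocular_jitter Maximum onset offset between the eyes in samples
#'   (default 1).
#' @param seed Integer top-level seed; trials use per-trial streams.
#' @return An object of class `fem_fixture`: list with `trials` (long
#'   binocular tibble `trial`, `eye`, `time`, `x`, `y` in degrees) and
#'   `events` (ground truth: `trial`, `onset`, `end`, `amplitude`, `angle`;
#'   indices are left-eye position samples).
#' @seealso [detect_binocular()], [match_episodes()]
#' @export
generate_trials <- function(n_trials = 30L, n_samples = 10000L, dt = 0.002,
                            drift = c("ndf", "brownian"), ms_rate = 1.5,
                            ms_amplitude_deg = 0.5, ms_amplitude_sd = 0.1,
                            ms_duration_ms = 24, noise_sd_deg = 0.01,
                            drift_sd_deg = 0.1, degree_scale = NULL,
                            binocular_jitter = 1L, seed = 1L) {
  drift <- match.arg(drift)
  dur <- as.integer(round(ms_duration_ms / 1000 / dt))
  stopifnot(n_trials >= 1, n_samples >= 50, ms_rate >= 0, ms_rate < 9,
            ms_duration_ms >= 6, noise_sd_deg >= 0, binocular_jitter >= 0)
  out <- purrr::map(seq_len(n_trials), function(tr) {
    s <- trial_seed(seed, tr)
    # drift positions (shared by both eyes), rescaled to degrees
    dr <- if (drift == "ndf") {
      simulate_ndf_2d(n_samples, seed = s, dt = dt)
    } else {
      set.seed(s)
      new_trajectory(cumsum(rnorm(n_samples)), cumsum(rnorm(n_samples)), dt = dt)
    }
    set.seed(trial_seed(s, 7L)) # event/noise stream, distinct from the drift stream
    dx <- dr$x - mean(dr$x); dy <- dr$y - mean(dr$y)
    scale <- if (is.null(degree_scale)) {
      drift_sd_deg / sqrt((stats::var(dx) + stats::var(dy)) / 2)
    } else {
      degree_scale
    }
    dx <- dx * scale; dy <- dy * scale

    # microsaccade onsets: refractory gap + exponential waiting time, so the
    # mean inter-event interval is 1/ms_rate
    onsets <- integer(0)
    if (ms_rate > 0) {
      gap_rate <- 1 / (1 / ms_rate - 0.1)
      tt <- 0.2 + rexp(1, gap_rate)
      while (TRUE) {
        o <- as.integer(round(tt / dt))
        if (o + dur + 5L > n_samples) break
        onsets <- c(onsets, o)
        tt <- tt + 0.1 + rexp(1, gap_rate)
      }
    }
    n_ev <- length(onsets)
    amps <- pmax(rnorm(n_ev, ms_amplitude_deg, ms_amplitude_sd), 0.1)
    ang_jit <- rnorm(n_ev, 0, 10 * pi / 180)
    jit <- if (binocular_jitter > 0 && n_ev > 0) {
      sample(seq.int(-binocular_jitter, binocular_jitter), n_ev, replace = TRUE)
    } else {
      rep(0L, n_ev)
    }

    # Each event corrects the current gaze offset (drift plus earlier events)
    # back towards the fixation target, moving predominantly along the
    # horizontal or vertical axis -- the error-correcting role that makes
    # the intact recording antipersistent on the long time scale. Direction
    # depends on the accumulated offset, so angles are resolved sequentially.
    angles <- numeric(n_ev)
    ms_offset <- function(onset_shift, resolve_angles = FALSE) {
      ox <- numeric(n_samples); oy <- numeric(n_samples)
      for (e in seq_len(n_ev)) {
        o <- onsets[[e]] + onset_shift[[e]]
        if (resolve_angles) {
          gaze <- c(dx[[o]] + ox[[o]], dy[[o]] + oy[[o]])
          axis_hor <- abs(gaze[[1]]) >= abs(gaze[[2]])
          base_ang <- if (axis_hor) {
            if (gaze[[1]] > 0) pi else 0
          } else {
            if (gaze[[2]] > 0) 1.5 * pi else 0.5 * pi
          }
          angles[[e]] <<- base_ang + ang_jit[[e]]
        }
        m <- seq_len(dur)
        prof <- amps[[e]] * (m / dur - sin(2 * pi * m / dur) / (2 * pi))
        idx <- o + m - 1L
        ox[idx] <- ox[idx] + prof * cos(angles[[e]])
        oy[idx] <- oy[idx] + prof * sin(angles[[e]])
        after <- seq.int(o + dur, n_samples)
        ox[after] <- ox[after] + amps[[e]] * cos(angles[[e]])
        oy[after] <- oy[after] + amps[[e]] * sin(angles[[e]])
      }
      list(x = ox, y = oy)
    }
    left_off <- ms_offset(rep(0L, n_ev), resolve_angles = TRUE)
    right_off <- ms_offset(jit)
    noise <- function() rnorm(n_samples, 0, noise_sd_deg)
    times <- (seq_len(n_samples) - 1) * dt
    trials <- bind_rows(
      tibble(trial = tr, eye = "left", time = times,
             x = dx + left_off$x + noise(), y = dy + left_off$y + noise()),
      tibble(trial = tr, eye = "right", time = times,
             x = dx + right_off$x + noise(), y = dy + right_off$y + noise())
    )
    events <- tibble(trial = tr, onset = onsets, end = onsets + dur - 1L,
                     amplitude = amps, angle = angles)
    list(trials = trials, events = events)
  })
  structure(
    list(
      trials = bind_rows(purrr::map(out, "trials")),
      events = bind_rows(purrr::map(out, "events")),
      dt = dt, n_trials = as.integer(n_trials),
      n_samples = as.integer(n_samples), seed = seed
    ),
    class = "fem_fixture"
  )
}

#' @export
print.fem_fixture <- function(x, ...) {
  cat(sprintf("<fem_fixture> %d binocular trial(s) x %d samples, %d injected microsaccade(s)\n",
              x$n_trials, x$n_samples, nrow(x$events)))
  invisible(x)
}

#' Match detected episodes against ground truth
#'
#' For each ground-truth event, looks for a detected episode whose interval
#' overlaps the (optionally padded) truth interval, and reports the onset
#' error of the closest match. Used to score detection recovery on
#' synthetic trials.
#'
#' @param detected Episode tibble with columns `onset`, `end` (and `trial`
#'   when `truth` has one).
#' @param truth Ground-truth tibble with columns `onset`, `end` (and
#'   optionally `trial`).
#' @param pad Padding in samples added to each side of the truth interval
#'   when testing for overlap (default 0).
#' @return `truth` with added columns `matched` (logical) and `onset_error`
#'   (samples; `NA` when unmatched).
#' @export
match_episodes <- function(detected, truth, pad = 0L) {
  stopifnot(all(c("onset", "end") %in% names(detected)),
            all(c("onset", "end") %in% names(truth)))
  by_trial <- "trial" %in% names(truth) && "trial" %in% names(detected)
  res <- purrr::map_dfr(seq_len(nrow(truth)), function(r) {
    tr <- truth[r, ]
    det <- if (by_trial) detected[detected$trial == tr$trial, ] else detected
    hit <- det$end >= tr$onset - pad & det$onset <= tr$end + pad
    if (any(hit)) {
      err <- min(abs(det$onset[hit] - tr$onset))
      tibble(matched = TRUE, onset_error = err)
    } else {
      tibble(matched = FALSE, onset_error = NA_real_)
    }
  })
  dplyr::bind_cols(truth, res)
}
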