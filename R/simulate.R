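#' Simulate a set of fixational eye movement trials
#'
#' Multi-trial front end for all models. Each trial runs on its own
#' reproducible stream ([trial_seed()]), so a trial can be regenerated in
#' isolation and trials could equally be run in parallel.
#'
#' @param model One of `"ndf"` (two-component non-linear delayed feedback
#'   drift), `"saw"` (fading self-avoiding walk), or a delayed variant
#'   `"ds"`, `"dr"`, `"da"`, `"dar"`.
#' @param n_trials Number of trials (default 30).
#' @param n_steps Samples per trial (default 10000, i.e. 20 s at 500 Hz).
#' @param seed Integer top-level seed.
#' @param params Model parameters: for `"ndf"` a list with elements `hor`
#'   and `ver` (each an [ndf_params()]); for the SAW family a
#'   [saw_params()] object (default as in [simulate_dsaw()]).
#' @param tau Delay in iterations for the D-SAW variants.
#' @param noise_sd,noise_enabled Read-out noise of the D-SAW variants.
#' @param dt Sample interval in seconds.
#' @return An object of class `fem_sim`: list with `trials` (long tibble
#'   `trial`, `time`, `x`, `y`), `events` (tibble `trial`, `step`, `time`,
#'   `from_x`, `from_y`, `to_x`, `to_y`; empty for `"ndf"`), and metadata
#'   (`model`, `n_trials`, `n_steps`, `seed`). Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' sim <- simulate_fem("saw", n_trials = 2, n_steps = 500, seed = 1,
#'                     params = saw_params(burn_in = 500))
#' glance(sim)
#' }
#' @export
simulate_fem <- function(model = c("ndf", "saw", "ds", "dr", "da", "dar"),
                         n_trials = 30L, n_steps = 10000L, seed = 1L,
                         params = NULL, tau = 15L, noise_sd = 0.3,
                         noise_enabled = TRUE, dt = 0.002) {
  model <- match.arg(model)
  stopifnot(n_trials >= 1, n_steps >= 1)
  empty_events <- tibble(trial = integer(), step = integer(), time = double(),
                         from_x = double(), from_y = double(),
                         to_x = double(), to_y = double())
  res <- purrr::map(seq_len(n_trials), function(tr) {
    s <- trial_seed(seed, tr)
    if (model == "ndf") {
      ph <- if (!is.null(params)) params$hor else ndf_params(tau = 35L)
      pv <- if (!is.null(params)) params$ver else ndf_params(tau = 20L)
      traj <- simulate_ndf_2d(n_steps, ph, pv, seed = s, dt = dt)
      list(traj = traj, events = NULL)
    } else if (model == "saw") {
      sim <- simulate_saw(n_steps, params = params %||% saw_params(),
                          seed = s, dt = dt)
      list(traj = sim$trajectory, events = sim$events)
    } else {
      sim <- simulate_dsaw(n_steps, variant = model, tau = tau, params = params,
                           noise_sd = noise_sd, noise_enabled = noise_enabled,
                           seed = s, dt = dt)
      list(traj = sim$trajectory, events = sim$events)
    }
  })
  trials <- purrr::map2_dfr(res, seq_len(n_trials),
                            ~ dplyr::bind_cols(tibble(trial = .y), .x$traj))
  ev <- purrr::map2(res, seq_len(n_trials), function(r, tr) {
    if (is.null(r$events) || nrow(r$events) == 0) return(NULL)
    dplyr::bind_cols(tibble(trial = tr), r$events)
  })
  ev <- purrr::compact(ev)
  events <- if (length(ev) > 0) bind_rows(ev) else empty_events
  structure(
    list(trials = trials, events = events, model = model,
         n_trials = as.integer(n_trials), n_steps = as.integer(n_steps),
         seed = seed, dt = dt),
    class = "fem_sim"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fem_sim <- function(x, ...) {
  cat(sprintf("<fem_sim: %s> %d trial(s) x %d steps (dt = %g s), %d event(s)\n",
              x$model, x$n_trials, x$n_steps, x$dt, nrow(x$events)))
  invisible(x)
}

#' Trial-averaged MSD and DACF curves
#'
#' Computes the time-averaged MSD and normalised DACF per trial and
#' component, then averages the curves across trials (means with per-lag
#' standard deviations). This is the standard characterisation pipeline for
#' both experimental and simulated fixation trials.
#'
#' @param trials Long tibble with columns `trial`, `time`, `x`, `y` (a
#'   single eye). A plain single-trajectory tibble is treated as one trial.
#' @param components Character vector from `"x"`, `"y"`, `"both"`; which
#'   movement components to analyse (default horizontal and vertical
#'   separately).
#' @param k DACF displacement interval in samples (default 25 = 50 ms).
#' @param msd_max_lag,dacf_max_lag Largest lags in samples (defaults cover
#'   1200 ms and 600 ms at 500 Hz).
#' @return A long tibble with columns `kind` (`"msd"`/`"dacf"`),
#'   `component`, `lag`, `lag_ms`, `value`, `sd`, `n`.
#' @examples
#' \donttest{
#' sim <- simulate_fem("ndf", n_trials = 3, n_steps = 3000, seed = 1)
#' curves <- fem_correlations(sim$trials, dacf_max_lag = 250)
#' }
#' @export
fem_correlations <- function(trials, components = c("x", "y"), k = 25L,
                             msd_max_lag = 600L, dacf_max_lag = 300L) {
  stopifnot(all(components %in% c("x", "y", "both")))
  tl <- trial_list(trials)
  purrr::map_dfr(components, function(cmp) {
    m <- average_curves(purrr::map(tl, ~ msd(.x, max_lag = msd_max_lag,
                                             component = cmp)))
    d <- average_curves(purrr::map(tl, ~ dacf(.x, k = k, max_lag = dacf_max_lag,
                                              component = cmp)))
    bind_rows(
      dplyr::bind_cols(tibble(kind = "msd", component = cmp), m),
      dplyr::bind_cols(tibble(kind = "dacf", component = cmp), d)
    )
  })
}
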