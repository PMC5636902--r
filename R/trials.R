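#' Deterministic per-trial random-number streams
#'
#' Trials are simulated on independent, reproducible streams: the stream seed
#' for trial `i` is a deterministic function of the top-level seed and `i`,
#' kept strictly below `2^31` so it is always a valid R integer seed. Running
#' a single trial in isolation with `trial_seed(seed, i)` reproduces exactly
#' that trial of a multi-trial simulation.
#'
#' @param seed Integer top-level seed.
#' @param trial Integer trial index (1-based).
#' @return A single integer seed.
#' @examples
#' trial_seed(1, 1)
#' trial_seed(1, 2)
#' @export
trial_seed <- function(seed, trial) {
  stopifnot(length(seed) == 1, length(trial) == 1, is.finite(seed), is.finite(trial))
  s <- (abs(as.double(seed)) %% 1000003) * 2039 + as.double(trial) * 9973 + 101
  as.integer(s %% 2147483647)
}

# Validate a single-trajectory data frame and return its numeric guts.
# A trajectory is a tibble with columns time (s), x, y; uniform sampling.
check_trajectory <- function(traj, min_n = 5L, arg = "traj") {
  if (!is.data.frame(traj)) {
    abort(sprintf("`%s` must be a data frame with columns time, x, y.", arg))
  }
  need <- c("time", "x", "y")
  miss <- setdiff(need, names(traj))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(miss, collapse = ", ")))
  }
  n <- nrow(traj)
  if (n < min_n) {
    abort(sprintf("`%s` has %d samples; at least %d are required.", arg, n, min_n))
  }
  x <- traj$x; y <- traj$y; tt <- traj$time
  if (anyNA(x) || anyNA(y) || anyNA(tt)) {
    abort(sprintf("`%s` contains missing samples; trials with gaps are rejected.", arg))
  }
  dt <- infer_dt(tt)
  list(x = as.double(x), y = as.double(y), time = as.double(tt), dt = dt, n = n)
}

# Infer a constant sample interval from a time column; reject non-uniform steps
# beyond a 1e-9 relative tolerance.
infer_dt <- function(time) {
  d <- diff(time)
  if (length(d) == 0) abort("time column too short to infer a sample interval.")
  dt <- stats::median(d)
  if (!is.finite(dt) || dt <= 0) abort("time column must be strictly increasing.")
  if (any(abs(d - dt) > 1e-9 * dt)) {
    abort("non-uniform sample interval: time steps deviate beyond 1e-9 relative tolerance.")
  }
  dt
}

#' Build a trajectory tibble from position vectors
#'
#' @param x,y Numeric position vectors (equal length).
#' @param dt Sample interval in seconds (default 0.002, i.e. 500 Hz).
#' @param t0 Time of the first sample (default 0).
#' @return A tibble with columns `time`, `x`, `y`.
#' @examples
#' new_trajectory(cumsum(rnorm(100)), cumsum(rnorm(100)))
#' @export
new_trajectory <- function(x, y, dt = 0.002, t0 = 0) {
  stopifnot(length(x) == length(y), dt > 0)
  tibble(time = t0 + (seq_along(x) - 1) * dt, x = as.double(x), y = as.double(y))
}

#' Read fixation trials from delimited text
#'
#' Reads a tab-separated file with one row per sample and columns `time`
#' (seconds), `x`, `y` (positions), plus optional `trial` and `eye` columns
#' for multi-trial / binocular files. Lines starting with `#` are treated as
#' comments; a comment of the form `# units: <label>` is attached to the
#' result as the `units` attribute. The sample interval is inferred from the
#' time column and must be constant (1e-9 relative tolerance); rows with
#' missing values are rejected, mirroring an acquisition policy that aborts
#' trials with gaps.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `time`, `x`, `y` and, when present,
#'   `trial` and `eye`; attribute `units` carries the unit label.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path) {
  header <- readLines(path, n = 50L)
  header <- header[startsWith(header, "#")]
  units <- NA_character_
  m <- grep("^#\\s*units:\\s*", header, value = TRUE)
  if (length(m) > 0) units <- sub("^#\\s*units:\\s*", "", m[[1]])
  # base parser: exact strtod round trip of %.17g-formatted doubles
  df <- as_tibble(utils::read.delim(path, sep = "\t", comment.char = "#",
                                    stringsAsFactors = FALSE))
  if (!all(c("time", "x", "y") %in% names(df))) {
    abort("file must contain columns time, x, y (optionally trial, eye).")
  }
  keep <- intersect(c("trial", "eye", "time", "x", "y"), names(df))
  df <- df[keep]
  if (nrow(df) > 0) {
    split_cols <- intersect(c("trial", "eye"), names(df))
    if (length(split_cols) == 0) {
      check_trajectory(df)
    } else {
      dts <- df |>
        group_by(dplyr::across(dplyr::all_of(split_cols))) |>
        dplyr::group_map(~ check_trajectory(.x)$dt)
      dts <- unlist(dts)
      if (diff(range(dts)) > 1e-9 * dts[[1]]) {
        abort("all trials must share the same sample interval.")
      }
    }
  }
  attr(df, "units") <- units
  df
}

#' Write fixation trials to delimited text
#'
#' Writes the long trial format read back by [read_trials()]: a commented
#' header carrying the unit label followed by tab-separated columns. Doubles
#' are written with round-trip precision.
#'
#' @param trials A tibble with columns `time`, `x`, `y` (optionally `trial`,
#'   `eye`).
#' @param path Output file path.
#' @param units Unit label recorded in the header comment (defaults to the
#'   `units` attribute of `trials`, else `"deg"`).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, units = NULL) {
  if (is.null(units)) units <- attr(trials, "units")
  if (is.null(units) || is.na(units)) units <- "deg"
  keep <- intersect(c("trial", "eye", "time", "x", "y"), names(trials))
  if (!all(c("time", "x", "y") %in% keep)) {
    abort("`trials` must contain columns time, x, y.")
  }
  out <- trials[keep]
  # %.17g survives the text round trip bit-exactly
  for (cl in keep) {
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  writeLines(sprintf("# units: %s", units), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

# Split a long multi-trial tibble into a named list of single trajectories.
# Used by grouped wrappers; `eye` (if present) must be filtered beforehand
# unless `allow_eye` is TRUE.
trial_list <- function(trials, allow_eye = FALSE) {
  if (!allow_eye && "eye" %in% names(trials) && length(unique(trials$eye)) > 1) {
    abort("`trials` contains multiple eyes; filter one eye (or use a binocular helper).")
  }
  if (!"trial" %in% names(trials)) {
    return(list(`1` = trials))
  }
  split(trials[setdiff(names(trials), "trial")], trials$trial)
}
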