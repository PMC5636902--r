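#' Plot trial-averaged correlation curves
#'
#' Displays the output of [fem_correlations()]: the MSD on log-log axes (the
#' scaling exponents are slopes in this view) and the DACF on a linear lag
#' axis, one panel per curve kind, coloured by component, with +/- 1 SD
#' ribbons across trials.
#'
#' @param curves Long curve tibble from [fem_correlations()] (columns
#'   `kind`, `component`, `lag_ms`, `value`, `sd`).
#' @return A ggplot object.
#' @export
plot_correlations <- function(curves) {
  stopifnot(all(c("kind", "component", "lag_ms", "value") %in% names(curves)))
  msd_part <- curves[curves$kind == "msd", ]
  dacf_part <- curves[curves$kind == "dacf" & curves$lag > 0, ]
  p_msd <- ggplot2::ggplot(msd_part,
                           ggplot2::aes(.data$lag_ms, .data$value,
                                        colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (ms)", y = "MSD", title = "Mean squared displacement")
  p_dacf <- ggplot2::ggplot(dacf_part,
                            ggplot2::aes(.data$lag_ms, .data$value,
                                         colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ms)", y = "DACF",
                  title = "Displacement autocorrelation")
  if ("sd" %in% names(curves)) {
    p_dacf <- p_dacf +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd,
                                        fill = .data$component),
                           alpha = 0.15, colour = NA)
  }
  if (requireNamespace("patchwork", quietly = TRUE)) {
    return(patchwork::wrap_plots(p_msd, p_dacf, ncol = 2))
  }
  p_dacf
}

#' Plot a simulated SAW run
#'
#' Path of the walker on the lattice with microsaccade jumps overlaid as
#' segments.
#'
#' @param object A `saw_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.saw_sim <- function(object, ...) {
  p <- ggplot2::ggplot(object$trajectory, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "horizontal (lattice units)", y = "vertical (lattice units)",
                  title = sprintf("%s walk, %d microsaccade(s)",
                                  toupper(object$variant), nrow(object$events)))
  if (nrow(object$events) > 0) {
    p <- p + ggplot2::geom_segment(
      data = object$events,
      ggplot2::aes(x = .data$from_x, y = .data$from_y,
                   xend = .data$to_x, yend = .data$to_y),
      colour = "red", arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt"))
    )
  }
  p
}

#' Plot the trials of a multi-trial simulation
#'
#' Horizontal and vertical position traces over time, faceted by trial (the
#' first few trials only, to stay legible).
#'
#' @param object A `fem_sim` object.
#' @param max_trials Number of trials displayed (default 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fem_sim <- function(object, max_trials = 4L, ...) {
  shown <- object$trials[object$trials$trial <= max_trials, ]
  long <- tidyr::pivot_longer(shown, c("x", "y"), names_to = "component",
                              values_to = "position")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$position,
                                     colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~trial) +
    ggplot2::labs(x = "time (s)", y = "position",
                  title = sprintf("%s simulation", object$model))
}

#' Plot a scaling-exponent fit over its window
#'
#' The windowed MSD points on log-log axes with the fitted power law.
#'
#' @param object A `fem_scaling` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fem_scaling <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$lag_ms, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(
      y = 10^(object$intercept + object$alpha * log10(.data$lag_ms / 1000))
    ), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (ms)", y = "MSD",
                  title = sprintf("alpha = %.3f over %.0f-%.0f ms", object$alpha,
                                  object$range_ms[[1]], object$range_ms[[2]]))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
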