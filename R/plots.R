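#' Plot amplification curves
#'
#' Per-well fluorescence against cycle, optionally with the analysis
#' window marked as horizontal lines and a log fluorescence axis (on
#' which exponential growth is a straight line).
#'
#' @param plate A [qpcr_plate()] with fluorescence data.
#' @param wells Optional subset of wells.
#' @param window Optional `c(lower, upper)` RFU window to draw.
#' @param log_y Log10 fluorescence axis (positive readings only).
#' @return A ggplot object.
#' @export
plot_amplification <- function(plate, wells = NULL, window = NULL,
                               log_y = FALSE) {
  stopifnot(inherits(plate, "qpcr_plate"))
  d <- plate$fluorescence
  if (!is.null(wells)) d <- filter(d, .data$well %in% wells)
  if (log_y) d <- filter(d, .data$rfu > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cycle, y = .data$rfu,
                                       group = .data$well,
                                       colour = .data$well)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Cycle", y = "Fluorescence (RFU)", colour = "Well") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::geom_hline(yintercept = window, linetype = "dashed")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn enumerate_pairs Histogram of the per-pair efficiency
#'   values at the diagnostic bin width, with optional exclusion
#'   cutoffs drawn as dashed lines.
#' @param object A `pairwise_e_array`.
#' @param bin_width Histogram bin width (default 0.05).
#' @param cutoffs Optional numeric cutoffs to mark.
#' @param ... Unused.
#' @export
autoplot.pairwise_e_array <- function(object, bin_width = 0.05,
                                      cutoffs = NULL, ...) {
  p <- ggplot2::ggplot(tibble(value = object$value),
                       ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            closed = "left", fill = "grey35") +
    ggplot2::labs(x = "Pairwise efficiency E", y = "Frequency") +
    ggplot2::theme_minimal()
  if (!is.null(cutoffs)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoffs, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' @describeIn monte_carlo_precision Histogram of the sampling means.
#' @param object An `mc_result`.
#' @export
autoplot.mc_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$mean_e)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35") +
    ggplot2::labs(
      x = "Sampling mean efficiency",
      y = "Frequency",
      title = if (!is.na(object$method)) object$method else NULL,
      subtitle = paste0("SD = ", signif(object$sd, 3))
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn noise_profile Histogram of the pooled early-cycle
#'   readings.
#' @param object A `noise_profile`.
#' @export
autoplot.noise_profile <- function(object, ...) {
  ggplot2::ggplot(tibble(rfu = object$values), ggplot2::aes(x = .data$rfu)) +
    ggplot2::geom_histogram(bins = max(10, nrow(object$histogram)),
                            fill = "grey35") +
    ggplot2::labs(x = "Fluorescence (RFU)", y = "Frequency") +
    ggplot2::theme_minimal()
}

#' @describeIn stable_region_scan Per-cycle efficiency under the
#'   candidate F0, with the stable span shaded.
#' @param object A `stable_region_scan`.
#' @export
autoplot.stable_region_scan <- function(object, ...) {
  ggplot2::ggplot(object$e_values, ggplot2::aes(x = .data$cycle, y = .data$e)) +
    ggplot2::annotate("rect", xmin = object$stable_span[1] - 0.5,
                      xmax = object$stable_span[2] + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Cycle", y = "Per-cycle efficiency E(i)") +
    ggplot2::theme_minimal()
}
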