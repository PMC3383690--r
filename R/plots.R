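#' Plot a record with detected events
#'
#' The current trace with detected event times marked; optionally the dense
#' deconvolved signal underneath.
#'
#' @param object A `blind_result`.
#' @param record The `ts_record` that was deconvolved.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blind_result <- function(object, record, ...) {
  df <- tibble(time_s = record$t0 + (seq_along(record$samples) - 1) * record$dt,
               current_pA = record$samples)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
  if (nrow(object$events)) {
    p <- p + ggplot2::geom_vline(
      data = as_tibble(object$events),
      ggplot2::aes(xintercept = .data$time_s),
      colour = "firebrick", alpha = 0.6, linewidth = 0.3)
  }
  p
}

#' Plot an accuracy curve
#'
#' Accuracy versus condition (pair separation or target amplitude) with
#' Wilson 95% confidence ribbons.
#'
#' @param object An `accuracy_curve` from [pairs_accuracy()] or
#'   [amplitude_accuracy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  unit <- attr(object, "condition_unit") %||% "condition"
  xlab <- if (identical(unit, "separation_s")) "separation (s)" else
    "target amplitude (pA)"
  ggplot2::ggplot(object, ggplot2::aes(.data$condition, .data$accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = xlab, y = "fraction of trials classified correctly") +
    ggplot2::theme_minimal()
}

#' Plot an impulse response (optionally against a reference)
#'
#' @param filter An `impulse_response`.
#' @param reference Optional second `impulse_response` drawn for comparison.
#' @return A ggplot object.
#' @export
plot_filter <- function(filter, reference = NULL) {
  df <- tibble(time_ms = (seq_along(filter$taps) - 1) * filter$dt * 1e3,
               value = filter$taps, which = "estimated")
  if (!is.null(reference)) {
    df <- dplyr::bind_rows(df, tibble(
      time_ms = (seq_along(reference$taps) - 1) * reference$dt * 1e3,
      value = reference$taps, which = "reference"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "impulse response (normalized)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Amplitude histogram with expected quantal grid
#'
#' @param amplitudes Amplitude magnitudes (pA or channel counts).
#' @param spacing Expected quantal spacing (same units); vertical guides are
#'   drawn at integer multiples.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_amplitude_histogram <- function(amplitudes, spacing = NULL, bins = 60) {
  df <- tibble(amplitude = abs(as.numeric(amplitudes)))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$amplitude)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "grey30") +
    ggplot2::labs(x = "amplitude magnitude", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(spacing)) {
    qs <- spacing * seq_len(floor(max(df$amplitude) / spacing))
    p <- p + ggplot2::geom_vline(xintercept = qs, linetype = 2,
                                 colour = "firebrick", alpha = 0.5)
  }
  p
}

#' @importFrom rlang .data
NULL
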