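#' Plot an area kymograph
#'
#' Renders the stacked rectangles with time progressing from top to bottom;
#' no-data cells are blank.
#'
#' @param object An `area_kymo` from [area_kymograph()].
#' @param ... Unused.
#' @param lut_range Display range; defaults to the object's `lut_range`.
#' @return A ggplot.
#' @method autoplot area_kymo
#' @export
autoplot.area_kymo <- function(object, ..., lut_range = NULL) {
  lut <- lut_range %||% object$lut_range
  df <- tidyr::expand_grid(row = seq_len(nrow(object$canvas)),
                           col = seq_len(ncol(object$canvas)))
  df$ratio <- as.vector(t(object$canvas))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$ratio)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::scale_fill_viridis_c(limits = lut, na.value = "grey92",
                                  name = "sense/ref") +
    ggplot2::labs(x = NULL, y = "time →", title = "Area kymograph") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot a ratio summary series as stylized boxplots
#'
#' @param object A `summary_series` from [frame_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot summary_series
#' @export
autoplot.summary_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = "time (min)", y = "sense/ref ratio",
                  title = "Wall-pixel ratio (median, IQR)") +
    ggplot2::theme_minimal()
}

#' Plot a growth trace
#'
#' @param object A `growth_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot growth_trace
#' @export
autoplot.growth_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min,
                                       y = .data$length_pct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "length (% of initial)") +
    ggplot2::theme_minimal()
}

#' Plot an onset fit
#'
#' Shows the trace, the two-segment fit and the estimated breakpoint.
#'
#' @param object An `onset_estimate` from [detect_onset()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot onset_estimate
#' @export
autoplot.onset_estimate <- function(object, ...) {
  df <- object$trace
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min,
                                        y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "value") +
    ggplot2::theme_minimal()
  if (object$onset_detected) {
    df$fitted <- object$fitted
    p <- p +
      ggplot2::geom_line(data = df, ggplot2::aes(y = .data$fitted),
                         colour = "firebrick") +
      ggplot2::geom_vline(xintercept = object$t_break_min,
                          linetype = "dashed") +
      ggplot2::labs(subtitle = sprintf("onset at %.3g min",
                                       object$t_break_min))
  } else {
    p <- p + ggplot2::labs(subtitle = "no onset detected")
  }
  p
}

#' Plot a bending-angle trace
#'
#' @param object A `bend_angle_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bend_angle_trace
#' @export
autoplot.bend_angle_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min,
                                       y = .data$angle_deg)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "tip angle (deg)",
                  subtitle = "0° horizontal, +90° vertical") +
    ggplot2::theme_minimal()
}
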