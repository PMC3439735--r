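#' Bar plot of predicted (and optionally measured) y-ion intensities
#'
#' @param predicted [predict_intensities()] output.
#' @param measured Optional tibble with `ion` and `rel_intensity`
#'   columns (e.g. [relative_intensities()] output).
#' @param series Ion series to show (default `"y"`).
#' @return A ggplot object.
#' @export
plot_intensities <- function(predicted, measured = NULL, series = "y") {
  df <- predicted[predicted$series %in% series,
                  c("ion", "rel_intensity")]
  df$source <- "predicted"
  if (!is.null(measured)) {
    m <- measured[measured$ion %in% df$ion, c("ion", "rel_intensity")]
    m$source <- "measured"
    df <- dplyr::bind_rows(df, m)
  }
  df$ion <- factor(df$ion, levels = sort(unique(df$ion)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ion,
                                   y = .data$rel_intensity,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = NULL, y = "relative intensity", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Log relative error plot for a comparison report
#'
#' One bar per compared ion showing log10(predicted/measured); the
#' logarithmic error scale makes order-of-magnitude prediction failures
#' visible next to sub-10% agreement.
#'
#' @param object A `comparison_report` from [log_error()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.comparison_report <- function(object, ...) {
  df <- tidy(object)
  df$ion <- factor(df$ion, levels = sort(unique(df$ion)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ion, y = .data$log_err)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL,
                  y = expression(log[10](predicted / measured))) +
    ggplot2::theme_minimal()
}
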