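# ggplot2 views of the main result types.

#' Heatmaps of a segmentation parameter screen
#'
#' One tile panel per quality metric over the diameter x flow-threshold
#' grid, mirroring how a parameter screen is usually inspected: the
#' segments-per-nucleus panel locates the count-accurate region, the FN/FP
#' panels show what it costs.
#'
#' @param object A `param_screen` tibble from [parameter_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.param_screen <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    c("segments_per_nucleus", "fn_ratio", "fp_ratio"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$diameter_px,
                                     y = .data$flow_threshold,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "diameter (px)", y = "flow threshold", fill = NULL)
}

#' Heatmap of a plate-screen summary
#'
#' @param object A `screen_summary` from [screen_summary()]; must carry the
#'   two condition-factor columns named in `x` and `y`.
#' @param metric Column to map to fill: `"frac_positive"`,
#'   `"rel_proliferation"` or `"total_positive"`.
#' @param x,y Names of the condition-factor columns spanning the plate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_summary <- function(object, metric = "frac_positive",
                                    x = "PE_ng", y = "MLH1_ng", ...) {
  df <- as_tibble(object)
  df <- df[!df$empty & !is.na(df[[x]]) & !is.na(df[[y]]), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data[[x]]),
                                   y = factor(.data[[y]]),
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = x, y = y, fill = metric)
}

#' Per-cell intensity histograms with gating thresholds
#'
#' Log10-scaled histograms of per-cell mean intensity, one panel per
#' channel, with the gating threshold drawn as a vertical line — the
#' standard visual check that the positive population sits clear of the
#' control-derived gate.
#'
#' @param records Tibble of cell records with `mean_<channel>` columns.
#' @param gates Optional `cyto_gates`; thresholds drawn when given.
#' @param channels Channels to plot; default all.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_intensity_histograms <- function(records, gates = NULL, channels = NULL,
                                      bins = 60) {
  records <- as_tibble(records)
  mean_cols <- grep("^mean_", names(records), value = TRUE)
  if (!is.null(channels)) mean_cols <- paste0("mean_", channels)
  long <- tidyr::pivot_longer(records[, mean_cols, drop = FALSE],
                              dplyr::everything(),
                              names_to = "channel", values_to = "intensity")
  long$channel <- sub("^mean_", "", long$channel)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$intensity)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::labs(x = "mean intensity (counts/px)", y = "cells")
  if (!is.null(gates))
    p <- p + ggplot2::geom_vline(
      data = tibble(channel = gates$channel, threshold = gates$threshold),
      ggplot2::aes(xintercept = .data$threshold), colour = "red")
  p
}
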