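# ggplot2 displays for the three result types. Figures mirror the field's
# standard renderings: kymograph heatmaps (time up, new pole left),
# demograph stacks (shortest cell on top), and super plots (per-cell cloud,
# replicate medians emphasised).

#' @describeIn grid_normalize_track Heatmap of a (single or average)
#'   kymograph: x = relative position (new pole -> old pole), y = relative
#'   cell-cycle time.
#' @param object A `kymograph`.
#' @param ... Unused.
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidy(object)
  n <- attr(object, "n_cells")
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$time,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::scale_x_continuous(expand = c(0, 0),
                                breaks = c(0, 0.5, 1),
                                labels = c("new pole", "mid-cell", "old pole")) +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::labs(
      x = "relative position", y = "relative cell-cycle time",
      title = if (is.null(n)) sprintf("Kymograph, cell %s", attr(object, "cell_id"))
      else sprintf("Average kymograph (n = %d cells, %s)", n,
                   attr(object, "normalization"))
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn build_demograph Heatmap of the demograph: one row per cell,
#'   shortest on top, brightest pole at the left edge.
#' @param object A `demograph`.
#' @param ... Unused.
#' @method autoplot demograph
#' @export
autoplot.demograph <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_index, .data$rank,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity", na.value = "grey90") +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "distance from brightest pole (px)",
                  y = "cells, sorted by length (cell-cycle proxy)",
                  title = sprintf("Demograph (n = %d cells)", nrow(object))) +
    ggplot2::theme_minimal()
}

#' Super plot of a per-cell measurement across strains and replicates
#'
#' Per-cell values as a jittered cloud colored by replicate, replicate
#' medians as large solid points, and the mean of the medians as a bar --
#' the display conventionally paired with a replicate-median paired ANOVA.
#'
#' @param measurements Tibble with `strain`, `replicate`, and the value
#'   column.
#' @param value Name of the value column (default `"share_old"`).
#' @return A ggplot object.
#' @export
plot_superplot <- function(measurements, value = "share_old") {
  med <- replicate_medians(measurements, value = value)
  measurements$replicate <- factor(measurements$replicate)
  med$replicate <- factor(med$replicate)
  ggplot2::ggplot(measurements,
                  ggplot2::aes(.data$strain, .data[[value]],
                               colour = .data$replicate)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.4, size = 1) +
    ggplot2::stat_summary(
      data = med, ggplot2::aes(y = .data$median_value, group = 1),
      fun = mean, geom = "crossbar", width = 0.5, colour = "black",
      linewidth = 0.4) +
    ggplot2::geom_point(data = med,
                        ggplot2::aes(y = .data$median_value), size = 3) +
    ggplot2::labs(x = NULL, y = value, colour = "replicate") +
    ggplot2::theme_classic()
}
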