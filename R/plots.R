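#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat-map of a delta-T1 slice
#'
#' Axial slice of a delta-T1 map, optionally restricted to a mask (the
#' per-lesion heat-map view used to judge whether T1 shortening is focal or
#' scattered). Negative values (gadolinium shortening) are blue.
#'
#' @param object A `delta_t1_map` from [compute_delta_t1()].
#' @param slice Axial slice index (default: middle slice).
#' @param mask Optional logical array; voxels outside it are blanked.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot delta_t1_map
#' @export
autoplot.delta_t1_map <- function(object, slice = NULL, mask = NULL, ...) {
  dat <- vol_data(object)
  if (is.null(slice)) slice <- round(dim(dat)[3] / 2)
  sl <- dat[, , slice]
  if (!is.null(mask)) sl[!vol_data(mask)[, , slice]] <- NA
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$delta_t1 <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$delta_t1)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "grey95",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "white",
                                  name = expression(Delta * T[1] ~ "(s)")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Delta-T1 map, axial slice %d", slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Density curve of a KDE summary
#'
#' @param object A [kde_summary()].
#' @param ... Unused.
#' @return A ggplot of the smoothed distribution.
#' @method autoplot kde_summary
#' @export
autoplot.kde_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$grid, .data$density)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "value", y = "density") +
    ggplot2::theme_minimal()
}

#' Group comparison of a subject-level delta-T1 metric
#'
#' Jittered points with group medians for one metric split by a grouping
#' column (phenotype, treatment, or the EDSS dichotomy).
#'
#' @param data A tibble with the metric and grouping columns (e.g. the
#'   [simulate_cohort()] output).
#' @param metric,group Column names (strings).
#' @return A ggplot.
#' @export
plot_group_comparison <- function(data, metric = "nel_delta_t1",
                                  group = "phenotype") {
  ggplot2::ggplot(data, ggplot2::aes(.data[[group]], .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.5) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.4, colour = "#B2182B") +
    ggplot2::labs(x = NULL, y = "NEL median delta-T1 (s)") +
    ggplot2::theme_minimal()
}

#' Overlaid per-subject KDE curves of voxelwise values
#'
#' The cohort-level distribution overlay: one smoothed curve per subject.
#'
#' @param pooled Output of [pooled_voxel_values()].
#' @param column Which voxel column to smooth (`"delta_t1"` or `"pre_t1"`).
#' @return A ggplot.
#' @export
plot_kde_overlay <- function(pooled, column = "delta_t1") {
  curves <- pooled |>
    dplyr::group_by(.data$subject) |>
    dplyr::filter(dplyr::n_distinct(.data[[column]]) >= 2) |>
    dplyr::group_modify(function(d, key) kde_summary(d[[column]])) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$grid, .data$density,
                               group = .data$subject, colour = .data$subject)) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = column, y = "density") +
    ggplot2::theme_minimal()
}
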