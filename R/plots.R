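# ggplot2 displays for the main result types.

#' Plot a voxelwise ICC map as axial slices
#'
#' @param object An [icc_map()] result (must carry a geometry).
#' @param ... Unused.
#' @return A ggplot object: per-slice heatmaps of voxelwise ICC.
#' @method autoplot icc_map
#' @export
autoplot.icc_map <- function(object, ...) {
  assert_that(!is.null(object$geometry), "icc_map has no geometry to plot")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$icc)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Voxelwise ICC(3,1)", fill = "ICC") +
    ggplot2::theme_minimal()
}

#' Plot a design matrix as a heatmap
#'
#' @param object A [build_design()] result.
#' @param ... Unused.
#' @return A ggplot object (regressors on x, scan time on y, SPM-style).
#' @method autoplot design_matrix
#' @export
autoplot.design_matrix <- function(object, ...) {
  df <- tidy(object)
  df$regressor <- factor(df$regressor, levels = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$regressor, y = .data$time,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = NULL, y = "time (s)",
                  title = paste("Design matrix:", object$spec$name)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot assumption-violation proportions per pipeline
#'
#' @param violation_table Output of [summarize_violations()] (or the
#'   `violation_table` element of a study result).
#' @return A ggplot bar chart, faceted by assumption.
#' @export
plot_violations <- function(violation_table) {
  ggplot2::ggplot(violation_table,
                  ggplot2::aes(x = .data$pipeline, y = .data$proportion,
                               fill = .data$pipeline)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~assumption) +
    ggplot2::labs(y = "proportion of models violating", x = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of voxelwise ICCs per pipeline with mvICC markers
#'
#' @param icc_maps Named list of [icc_map()] results (one per pipeline).
#' @param roi Optional voxel positions restricting the histogram.
#' @return A ggplot object.
#' @export
plot_icc_histograms <- function(icc_maps, roi = NULL) {
  df <- purrr::map_dfr(names(icc_maps), function(pn) {
    v <- icc_maps[[pn]]$icc
    if (!is.null(roi)) v <- v[roi]
    tibble(pipeline = pn, icc = v[!is.na(v)])
  })
  med <- df |>
    dplyr::group_by(.data$pipeline) |>
    dplyr::summarise(mvicc = median(.data$icc), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(data = med, ggplot2::aes(xintercept = .data$mvicc),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~pipeline) +
    ggplot2::labs(x = "voxelwise ICC(3,1)", y = "voxels") +
    ggplot2::theme_minimal()
}
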