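#' Plot a colored point cloud
#'
#' Orthographic projection of the cloud onto a coordinate plane, each point
#' drawn in its own RGB color.
#'
#' @param object A [point_cloud()].
#' @param plane `"xz"` (side view, default), `"yz"`, or `"xy"` (top view).
#' @param size Point size.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.point_cloud <- function(object, plane = c("xz", "yz", "xy"),
                                 size = 0.3, ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  df <- tibble::as_tibble(object)
  df$col <- grDevices::rgb(df$r, df$g, df$b, maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]])) +
    ggplot2::geom_point(color = df$col, size = size) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = ax[1], y = ax[2]) +
    ggplot2::theme_minimal()
}

#' Plot a segmentation, one color per region
#'
#' @param object A `plant_segmentation`.
#' @param cloud The segmented [point_cloud()].
#' @param plane Projection plane as in [autoplot.point_cloud()].
#' @param size Point size.
#' @param ... Unused.
#' @return A ggplot with regions colored categorically and the stem region
#'   named in the legend.
#' @export
autoplot.plant_segmentation <- function(object, cloud,
                                        plane = c("xz", "yz", "xy"),
                                        size = 0.3, ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  df <- segmentation_tibble(object, cloud)
  df$region <- factor(ifelse(df$label < 0, "unassigned",
                             paste0(df$kind, " ", df$label)))
  ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                   color = .data$region)) +
    ggplot2::geom_point(size = size) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = ax[1], y = ax[2], color = "region") +
    ggplot2::theme_minimal()
}

#' Agreement scatter plot with the fitted line
#'
#' @param object An [agreement_stats()] fit.
#' @param pairs The pairs the fit was computed on (columns `reference`,
#'   `measured`).
#' @param ... Unused.
#' @return A ggplot of measured vs reference with the identity and OLS lines.
#' @export
autoplot.agreement_fit <- function(object, pairs, ...) {
  ggplot2::ggplot(pairs, ggplot2::aes(.data$reference, .data$measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "forestgreen") +
    ggplot2::geom_point() +
    ggplot2::labs(
      subtitle = sprintf("R² = %.3f, RMSE = %.2f, n = %d",
                         object$r_squared, object$rmse, object$n)) +
    ggplot2::theme_minimal()
}

#' Per-stage point-count bar chart
#'
#' The familiar before/after-filtering comparison: raw count, after color
#' filtering, after voxel filtering.
#'
#' @param result A [run_pipeline()] result.
#' @return A ggplot.
#' @export
plot_stage_counts <- function(result) {
  df <- result$stage_counts
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$n_points)) +
    ggplot2::geom_col(fill = "forestgreen") +
    ggplot2::labs(x = NULL, y = "points") +
    ggplot2::theme_minimal()
}
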