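#' Plot PCA scores colored by individual, shaped by device
#'
#' @param object A `shape_pca`.
#' @param x_axis,y_axis Components to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_pca <- function(object, x_axis = 1, y_axis = 2, ...) {
  sc <- object$scores
  xv <- paste0("PC", x_axis)
  yv <- paste0("PC", y_axis)
  gg <- ggplot2::ggplot(sc, ggplot2::aes(.data[[xv]], .data[[yv]]))
  if ("individual" %in% names(sc)) {
    gg <- gg + ggplot2::aes(colour = .data$individual)
  }
  if ("device" %in% names(sc)) gg <- gg + ggplot2::aes(shape = .data$device)
  gg + ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xv, object$variance_explained[x_axis]),
      y = sprintf("%s (%.1f%%)", yv, object$variance_explained[y_axis])
    ) +
    ggplot2::theme_minimal() +
    ggplot2::guides(colour = "none")
}

#' Box plot of per-cell Procrustes variance by device
#'
#' @param object A `gm_disparity` from [procrustes_variance_by_group()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gm_disparity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$device, .data$variance)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::labs(
      x = NULL, y = "Procrustes variance (replicates around cell mean)"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of percent variance per ANOVA factor
#'
#' @param object A `procrustes_anova`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.procrustes_anova <- function(object, ...) {
  pv <- percent_variance(object)
  pv$term <- factor(pv$term, levels = pv$term)
  ggplot2::ggplot(pv, ggplot2::aes(.data$term, .data$pct_var)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of total shape variation") +
    ggplot2::theme_minimal()
}
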