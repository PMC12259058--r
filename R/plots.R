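# ggplot2 views of the main result types.

#' Plot a cell table
#'
#' Cell centers colored by phenotype (or any other column), with ROI
#' rectangles overlaid when supplied. y is reversed to match the image
#' convention (origin top-left).
#'
#' @param cells A cell table.
#' @param colour Column name used for the color aesthetic (default
#'   `"phenotype"`).
#' @param rois Optional `nbhood_roi` tibble drawn as rectangles.
#' @return A ggplot object.
#' @export
plot_tissue <- function(cells, colour = "phenotype", rois = NULL) {
  p <- ggplot2::ggplot(tibble::as_tibble(as.data.frame(cells)),
                       ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                    colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = colour) +
    ggplot2::theme_minimal()
  if (!is.null(rois)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(as.data.frame(rois)),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, fill = NA, colour = "grey30",
      linetype = "dashed"
    )
  }
  p
}

#' @export
autoplot.nbhood_sim <- function(object, ...) {
  cells <- object$cells
  cells$phenotype <- cells$true_type
  plot_tissue(cells, rois = object$roi) +
    ggplot2::ggtitle("Synthetic tissue (ground-truth types)")
}

#' @export
autoplot.nbhood_region_summary <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_class, y = .data$mean,
                                   fill = .data$region_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.2
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean ± SEM") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot neighborhood composition
#'
#' Distribution of per-focal-cell neighbor fractions by phenotype.
#'
#' @param composition Output of [neighborhood_composition()].
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  df <- dplyr::filter(composition, !.data$empty)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype, y = .data$fraction)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "neighbor phenotype",
                  y = "fraction of neighbors (per focal cell)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
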