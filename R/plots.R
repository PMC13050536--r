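#' Bar chart of the regulatory-element class distribution
#'
#' @param object A `cre_annotation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cre_annotation
#' @export
autoplot.cre_annotation <- function(object, ...) {
  dist <- class_distribution(object)
  ggplot2::ggplot(dist, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$n),
    y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percentage)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of candidate regions",
                  title = "Regulatory element distribution") +
    ggplot2::theme_minimal()
}

#' Heatmap of a coverage metaplot matrix
#'
#' Rows are regions in their supplied stacking order (top row first), columns
#' the position bins relative to region centres.
#'
#' @param object A `cre_metaplot` matrix from [compute_metaplot()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cre_metaplot
#' @export
autoplot.cre_metaplot <- function(object, ...) {
  long <- tidy.cre_metaplot(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$row,
                                     fill = .data$coverage)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "distance from region centre (bp)", y = "region",
                  fill = "coverage") +
    ggplot2::theme_minimal()
}

#' Mean coverage profile of a metaplot matrix
#'
#' @param mp A `cre_metaplot` matrix.
#' @return A ggplot object: mean coverage per position bin.
#' @export
plot_metaplot_profile <- function(mp) {
  prof <- tibble(position = as.numeric(colnames(mp)),
                 coverage = colMeans(unclass(mp)))
  ggplot2::ggplot(prof, ggplot2::aes(.data$position, .data$coverage)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "distance from region centre (bp)",
                  y = "mean coverage") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
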