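#' CNA heatmap
#'
#' Cells as rows, genome-ordered positions as columns, inferred relative
#' copy number as fill (blue = deletion, red = amplification), with
#' chromosome boundaries marked. Cells can be grouped (e.g. by cell type
#' or subclone) to reproduce the familiar tumour-vs-reference panels.
#'
#' @param object a [cna_matrix()].
#' @param groups optional named vector (cell id -> group) used to order
#'   and facet the rows.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cna_matrix
#' @export
autoplot.cna_matrix <- function(object, groups = NULL, ...) {
  long <- tidy.cna_matrix(object)
  if (!is.null(groups)) {
    long$group <- groups[long$cell_id]
    long$cell_id <- factor(long$cell_id,
                           names(sort(rank(groups, ties.method = "first"))))
  }
  lim <- max(abs(long$cna), 0.15)
  bounds <- cumsum(rle(object$annotation$chromosome)$lengths)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$order_index, y = .data$cell_id, fill = .data$cna
  )) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = object$annotation$order_index[
      pmin(bounds, nrow(object$annotation))
    ] + 0.5, linewidth = 0.2, colour = "grey30") +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "white", high = "#B2182B",
      limits = c(-lim, lim), name = "CNA"
    ) +
    ggplot2::labs(x = "genome position (ordered genes)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (!is.null(groups)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$group),
                                 scales = "free_y", space = "free_y")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' CNA signal vs CNA correlation scatter
#'
#' Each point is a cell; dashed lines mark the median + k SD cutoffs
#' derived from the reference cells. Cells above both lines are the
#' malignant calls.
#'
#' @param object a `cna_classification` from [classify_cells()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cna_classification
#' @export
autoplot.cna_classification <- function(object, ...) {
  r <- object$records
  ggplot2::ggplot(r, ggplot2::aes(
    x = .data$cna_signal, y = .data$cna_correlation,
    colour = ifelse(.data$malignant, "malignant",
                    ifelse(.data$is_reference, "reference", "other"))
  )) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_vline(xintercept = object$cutoffs$signal_cutoff,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$cutoffs$correlation_cutoff,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      malignant = "#B2182B", reference = "#2166AC", other = "grey50"
    ), name = NULL) +
    ggplot2::labs(x = "CNA signal", y = "CNA correlation") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cna_matrix
#' @param cna a [cna_matrix()].
#' @export
plot_cna_heatmap <- function(cna, groups = NULL) {
  autoplot.cna_matrix(cna, groups = groups)
}

#' @rdname autoplot.cna_classification
#' @param classification a `cna_classification`.
#' @export
plot_classification <- function(classification) {
  autoplot.cna_classification(classification)
}
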