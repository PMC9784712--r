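# ggplot2 graphics for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

subtype_fill_scale <- function() {
  ggplot2::scale_colour_manual(
    values = c(CL = "#3B6FB6", MES = "#C23B3B", PN = "#3E9B4F"),
    aesthetics = c("colour", "fill"), drop = FALSE)
}

#' Plot one-vs-rest ROC curves
#'
#' @param x A `subtype_roc` from [roc_one_vs_rest()].
#' @param ... Unused.
#' @return A ggplot object with one curve per subtype, AUC in the legend.
#' @export
plot_roc <- function(x, ...) {
  if (!inherits(x, "subtype_roc")) abort("`x` must be a subtype_roc")
  lab <- x$auc |>
    dplyr::mutate(label = sprintf("%s (AUC %.3f)", .data$subtype, .data$auc))
  curves <- dplyr::left_join(x$curves, lab, by = "subtype")
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL, title = "One-vs-rest ROC") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.subtype_roc <- function(object, ...) plot_roc(object, ...)

#' Plot an MDS embedding with subtype centroids
#'
#' @param x A `subtype_mds` from [mds_centroid_distances()].
#' @param ... Unused.
#' @return A ggplot object: samples coloured by subtype, centroids as
#'   diamonds, dashed segments between centroids annotated with their
#'   Euclidean distance.
#' @export
plot_mds <- function(x, ...) {
  if (!inherits(x, "subtype_mds")) abort("`x` must be a subtype_mds")
  cent <- x$coords |>
    dplyr::group_by(.data$subtype) |>
    dplyr::summarise(dim1 = mean(.data$dim1), dim2 = mean(.data$dim2),
                     .groups = "drop")
  pairs <- utils::combn(seq_len(nrow(cent)), 2)
  segs <- tibble::tibble(
    x = cent$dim1[pairs[1, ]], y = cent$dim2[pairs[1, ]],
    xend = cent$dim1[pairs[2, ]], yend = cent$dim2[pairs[2, ]],
    d = sprintf("d = %.2f", sqrt((cent$dim1[pairs[1, ]] - cent$dim1[pairs[2, ]])^2 +
                                   (cent$dim2[pairs[1, ]] - cent$dim2[pairs[2, ]])^2))
  )
  ggplot2::ggplot(x$coords, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          inherit.aes = FALSE, linetype = "dashed",
                          colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$subtype), alpha = 0.7) +
    ggplot2::geom_point(data = cent,
                        ggplot2::aes(fill = .data$subtype), shape = 23,
                        size = 4, colour = "black") +
    ggplot2::geom_text(data = cbind(segs, tibble::tibble(
      mx = (segs$x + segs$xend) / 2, my = (segs$y + segs$yend) / 2)),
      ggplot2::aes(x = .data$mx, y = .data$my, label = .data$d),
      inherit.aes = FALSE, size = 3, vjust = -0.5) +
    subtype_fill_scale() +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "Subtype", fill = "Subtype") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.subtype_mds <- function(object, ...) plot_mds(object, ...)

#' Plot cumulative feature-selection scores
#'
#' @param x A `gene_ranking` from [aggregate_rankings()].
#' @param ... Unused.
#' @return A ggplot bar chart of cumulative scores, selected panel genes
#'   highlighted.
#' @export
plot_cumulative_scores <- function(x, ...) {
  if (!inherits(x, "gene_ranking")) abort("`x` must be a gene_ranking")
  dat <- dplyr::mutate(tibble::as_tibble(x),
                       gene = factor(.data$gene, levels = rev(.data$gene)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$cumulative, .data$gene,
                                    fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#C23B3B", `FALSE` = "grey70"),
                               labels = c(`TRUE` = "in panel", `FALSE` = "not selected")) +
    ggplot2::labs(x = "Cumulative mean-normalised score", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gene_ranking <- function(object, ...) plot_cumulative_scores(object, ...)

#' Bi-clustered expression heatmap
#'
#' Standardised expression tiled in the leaf orders of [bicluster_order()],
#' with an optional subtype annotation strip above the samples.
#'
#' @param x Wide expression tibble (or genes x samples matrix); typically
#'   z-scored first.
#' @param labels Optional subtype labels for the annotation strip.
#' @param cluster Reorder rows/columns by hierarchical bi-clustering
#'   (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_subtype_heatmap <- function(x, labels = NULL, cluster = TRUE) {
  m <- expr_mat(x)
  if (cluster) {
    ord <- bicluster_order(m)
    m <- m[ord$row_order, ord$col_order, drop = FALSE]
  }
  dat <- expr_tbl(m) |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value") |>
    dplyr::mutate(gene = factor(.data$gene, levels = rev(rownames(m))),
                  sample = factor(.data$sample, levels = colnames(m)))
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$sample, .data$gene,
                                         fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(labels)) {
    y <- align_labels(labels, colnames(m))
    strip <- tibble::tibble(sample = factor(colnames(m), levels = colnames(m)),
                            subtype = as.character(y))
    p <- p + ggplot2::geom_tile(
      data = strip,
      ggplot2::aes(x = .data$sample, y = length(levels(dat$gene)) + 1.2,
                   fill = NULL, colour = .data$subtype),
      height = 0.6, linewidth = 1.2, inherit.aes = FALSE) +
      subtype_fill_scale()
  }
  p
}
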