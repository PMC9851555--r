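#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
#' @rdname run_pipeline
#' @param x A `dupshift_report`.
#' @param ... Unused.
glance.dupshift_report <- function(x, ...) {
  tibble(n_candidates = nrow(x$candidates),
         n_columns_kept = x$alignment$n_columns_kept,
         inner_monophyletic = x$clades$inner_monophyletic,
         nested_within_parent = x$clades$nested_within_parent,
         inner_clade_support = x$clades$inner_clade_support,
         n_genomes_with_duplicate = sum(x$synteny$duplicate_in_block),
         n_coexpression_edges = if (is.null(x$coexpression)) NA_integer_
                                else nrow(x$coexpression))
}

#' @export
#' @rdname run_pipeline
tidy.dupshift_report <- function(x, ...) {
  x$residue_table
}

#' @export
#' @rdname coexpression
tidy.coexpression_result <- function(x, ...) {
  as_tibble(x)
}

#' Rank plot of co-expression partners
#'
#' @param object A [coexpression()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coexpression_result <- function(object, ...) {
  df <- as_tibble(object)
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$gene)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Spearman rho", y = NULL,
                  title = sprintf("Co-expression partners of %s",
                                  attr(object, "focal"))) +
    ggplot2::theme_minimal()
}

#' Violin-style tissue expression plot
#'
#' @param summary A [tissue_summary()] tibble.
#' @return A ggplot of per-tissue TPM distributions, one panel per gene.
#' @export
plot_tissue_expression <- function(summary) {
  long <- tidyr::unnest(summary[, c("gene", "tissue", "values")],
                        "values")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tissue, y = .data$values)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::geom_point(alpha = 0.3, size = 0.6,
                        position = ggplot2::position_jitter(width = 0.1)) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "TPM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Microsynteny ribbon plot
#'
#' Draws the gene orders of two genomes as rows of boxes and connects
#' chained anchor pairs, highlighting a focal family.
#'
#' @param order_a,order_b Gene-order tibbles ([read_gene_order()] shape).
#' @param blocks A [chain_anchors()] result for the pair.
#' @param family_ids Character vector of focal family gene ids (both
#'   genomes) to highlight.
#' @param window Optional integer vector of A-side order indices to show.
#' @return A ggplot.
#' @export
plot_synteny <- function(order_a, order_b, blocks, family_ids = character(),
                         window = NULL) {
  anc <- dplyr::bind_rows(blocks$anchors)
  if (!is.null(window)) {
    anc <- anc[anc$idx_a %in% window, ]
    order_a <- order_a[order_a$order %in% window, ]
    order_b <- order_b[order_b$order %in%
                         seq(min(anc$idx_b), max(anc$idx_b)), ]
  }
  genes <- dplyr::bind_rows(
    dplyr::mutate(order_a, y = 1, idx = .data$order),
    dplyr::mutate(order_b, y = 0, idx = .data$order))
  genes$focal <- genes$gene_id %in% family_ids
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = anc,
                          ggplot2::aes(x = .data$idx_a, xend = .data$idx_b,
                                       y = 0.95, yend = 0.05),
                          color = "grey70") +
    ggplot2::geom_tile(data = genes,
                       ggplot2::aes(x = .data$idx, y = .data$y,
                                    fill = .data$focal),
                       width = 0.8, height = 0.08, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "skyblue",
                                          `TRUE` = "orange")) +
    ggplot2::labs(x = "gene order index", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
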