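#' MA plot of a differential-expression result
#'
#' Mean normalized expression (log10) against log2 fold change, significant
#' genes highlighted.
#'
#' @param object An `nb_de` object from [nb_wald_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nb_de <- function(object, ...) {
  d <- tidy(object)
  d$mean_expr <- (d$base_mean_a + d$base_mean_b) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$mean_expr + 0.5),
                                  y = .data$log2fc,
                                  colour = .data$call != "ns")) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 labels = c("ns", "DE"), name = NULL) +
    ggplot2::labs(x = "log10 mean normalized count",
                  y = "log2 fold change",
                  title = paste(object$comparison, collapse = " vs ")) +
    ggplot2::theme_minimal()
}

#' Z-score heat map with clustered samples
#'
#' @param clust A `zscore_clust` object from [zscore_cluster()].
#' @param max_genes Genes shown (most variable first, default 500).
#' @return A ggplot of gene x sample z-score tiles, samples in dendrogram
#'   leaf order.
#' @export
plot_zscore_heatmap <- function(clust, max_genes = 500) {
  z <- counts_to_matrix(clust$z)
  if (nrow(z) > max_genes) {
    spread <- apply(z, 1, function(r) diff(range(r)))
    z <- z[order(-spread)[seq_len(max_genes)], , drop = FALSE]
  }
  long <- tibble::as_tibble(z, rownames = "locus_tag") |>
    tidyr::pivot_longer(-"locus_tag", names_to = "sample_id",
                        values_to = "z") |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = clust$order))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$locus_tag,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = paste(nrow(z), "genes"), fill = "z")
}

#' PCA diagnostic of samples
#'
#' Principal components of log-scale normalized expression, as an outlier /
#' replicate-agreement screen. Diagnostic only; no samples are removed.
#'
#' @param normalized Tibble with `locus_tag` plus sample columns.
#' @param design Optional design tibble (`sample_id`, `condition`) for
#'   coloring.
#' @return A ggplot of PC1 vs PC2.
#' @export
plot_sample_pca <- function(normalized, design = NULL) {
  m <- counts_to_matrix(normalized)
  pc <- stats::prcomp(t(log2(m + 1)), center = TRUE, scale. = FALSE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  d <- tibble::tibble(sample_id = colnames(m),
                      PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  if (!is.null(design)) {
    d <- dplyr::left_join(d, design[, c("sample_id", "condition")],
                          by = "sample_id")
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                         colour = .data$condition))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
                       vjust = -0.8, size = 2.8, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' Motif-position plot
#'
#' Hit distances from the start codon per promoter, one row per locus tag,
#' colored by pattern — the triangle-track view of binding-site positions.
#'
#' @param hits Tibble from [scan_promoters()].
#' @param promoter_length Axis limit (default 200).
#' @return A ggplot.
#' @export
plot_motif_positions <- function(hits, promoter_length = 200) {
  ggplot2::ggplot(hits, ggplot2::aes(x = -.data$distance, y = .data$locus_tag,
                                     colour = .data$pattern_id,
                                     shape = .data$pattern_id)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(17, 25, 15, 16)) +
    ggplot2::xlim(-promoter_length, 0) +
    ggplot2::labs(x = "position upstream of start codon (bp)", y = NULL,
                  colour = "motif", shape = "motif") +
    ggplot2::theme_minimal()
}
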