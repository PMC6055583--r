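#' Volcano plot of a differential result
#'
#' @param object A `diff_result`.
#' @param fdr FDR threshold used to colour significant features
#'   (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diff_result
#' @export
autoplot.diff_result <- function(object, fdr = 0.05, ...) {
  df <- tidy(object)
  df$significant <- df$q <= fdr
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      title = sprintf("%s, %s", attr(object, "layer"), attr(object, "contrast")),
      x = "log2 fold change", y = expression(-log[10](p)),
      colour = sprintf("q ≤ %g", fdr)) +
    ggplot2::theme_minimal()
}

#' Sample scores of a PCA separation analysis
#'
#' @param object A `pca_separation` result.
#' @param ... Unused.
#' @return A ggplot object of PC1 vs PC2 coloured by tissue grade.
#' @method autoplot pca_separation
#' @export
autoplot.pca_separation <- function(object, ...) {
  ve <- attr(object, "var_explained")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                       colour = .data$grade)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      title = sprintf("PCA on significant features (%s)",
                      if (attr(object, "separated")) "separated" else "not separated"),
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}

#' Scatter of log fold changes between two differential results
#'
#' Visualises the cross-contrast (or cross-layer) effect structure
#' summarised by [contrast_correlation()].
#'
#' @param diff_a,diff_b `diff_result` tibbles sharing features.
#' @param fdr Colour features significant in `diff_a` at this FDR
#'   (default 0.001).
#' @return A ggplot object.
#' @export
plot_contrast_concordance <- function(diff_a, diff_b, fdr = 0.001) {
  shared <- intersect(diff_a$feature, diff_b$feature)
  a <- diff_a[match(shared, diff_a$feature), ]
  b <- diff_b[match(shared, diff_b$feature), ]
  df <- tibble(x = a$logFC, y = b$logFC, significant = a$q <= fdr)
  lab_a <- sprintf("logFC %s (%s)", attr(diff_a, "contrast"), attr(diff_a, "layer"))
  lab_b <- sprintf("logFC %s (%s)", attr(diff_b, "contrast"), attr(diff_b, "layer"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = lab_a, y = lab_b, colour = sprintf("q ≤ %g", fdr)) +
    ggplot2::theme_minimal()
}
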