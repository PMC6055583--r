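#' Restrict a gene-ID mapping table to one-to-one pairs
#'
#' Keeps only rows where both the Ensembl gene ID and the gene name occur
#' exactly once in the table, so that a unique ID corresponds to a unique
#' name.
#'
#' @param mapping Data frame with columns `ensembl_id` and `gene_name`.
#' @return A tibble of the retained one-to-one pairs, original order.
#' @export
map_gene_ids <- function(mapping) {
  stopifnot(all(c("ensembl_id", "gene_name") %in% names(mapping)))
  mapping <- as_tibble(mapping)
  id_n <- table(mapping$ensembl_id)
  nm_n <- table(mapping$gene_name)
  mapping[id_n[mapping$ensembl_id] == 1L & nm_n[mapping$gene_name] == 1L, ]
}

#' Genes significant on all three omics layers
#'
#' Returns the genes significant at `fdr` on both the RNA and protein layers
#' that also overlap a DMR, with per-layer directions, an RNA-protein
#' directional-concordance flag, and (when the osteophytic-vs-high results
#' are supplied) a flag marking support on all three layers at
#' `secondary_fdr` in that contrast.
#'
#' Methylation direction is `prop_pos_beta >= 0.5` (majority of the gene's
#' DMPs hypermethylated in the first-named tissue).
#'
#' @param rna,protein Gene-level `diff_result` tibbles for one contrast.
#' @param dmr_genes Tibble from [overlap_genes()] (or character vector of
#'   genes overlapped by DMRs).
#' @param fdr FDR threshold applied to RNA and protein (default 0.001).
#' @param secondary Optional list with elements `rna`, `protein`
#'   (`diff_result`s for the secondary contrast) and `dmr_genes`.
#' @param secondary_fdr Threshold for the secondary-support flag
#'   (default 0.05).
#' @return A `cross_omics_genes` tibble, one row per triple-significant
#'   gene.
#' @export
triple_overlap <- function(rna, protein, dmr_genes, fdr = 0.001,
                           secondary = NULL, secondary_fdr = 0.05) {
  dmr_tbl <- if (is.character(dmr_genes)) {
    tibble(gene = dmr_genes, n_dmps_in_dmrs = NA_integer_,
           prop_pos_beta = NA_real_)
  } else as_tibble(dmr_genes)
  sig_rna <- rna[rna$q <= fdr, c("feature", "logFC", "q")]
  sig_prot <- protein[protein$q <= fdr, c("feature", "logFC", "q")]
  genes <- sort(intersect(intersect(sig_rna$feature, sig_prot$feature),
                          dmr_tbl$gene))
  out <- tibble(
    gene = genes,
    n_dmps_in_dmrs = dmr_tbl$n_dmps_in_dmrs[match(genes, dmr_tbl$gene)],
    prop_pos_beta = dmr_tbl$prop_pos_beta[match(genes, dmr_tbl$gene)],
    rna_logFC = sig_rna$logFC[match(genes, sig_rna$feature)],
    rna_q = sig_rna$q[match(genes, sig_rna$feature)],
    protein_logFC = sig_prot$logFC[match(genes, sig_prot$feature)],
    protein_q = sig_prot$q[match(genes, sig_prot$feature)]
  )
  out$rna_direction <- sign(out$rna_logFC)
  out$protein_direction <- sign(out$protein_logFC)
  out$meth_direction <- ifelse(is.na(out$prop_pos_beta), NA,
                               ifelse(out$prop_pos_beta >= 0.5, 1, -1))
  out$rna_protein_concordant <- out$rna_direction == out$protein_direction
  if (!is.null(secondary)) {
    sec_dmr <- if (is.character(secondary$dmr_genes)) secondary$dmr_genes
               else secondary$dmr_genes$gene
    out$o_vs_h_supported <-
      out$gene %in% significant_features(secondary$rna, secondary_fdr) &
      out$gene %in% significant_features(secondary$protein, secondary_fdr) &
      out$gene %in% sec_dmr
  } else {
    out$o_vs_h_supported <- NA
  }
  class(out) <- c("cross_omics_genes", class(out))
  out
}

#' Exact one-sided binomial concordance test
#'
#' Exact upper-tail probability `P(X >= n_concordant)` for
#' `X ~ Binomial(n_total, 0.5)` by summation (no normal approximation),
#' testing whether directional agreement between two layers exceeds chance.
#'
#' @param n_concordant Number of concordant genes.
#' @param n_total Total number of genes compared.
#' @return The one-sided P-value.
#' @export
binomial_concordance <- function(n_concordant, n_total) {
  check_number(n_total, "n_total", lower = 1, integer = TRUE)
  check_number(n_concordant, "n_concordant", lower = 0, upper = n_total,
               integer = TRUE)
  pbinom(n_concordant - 1, size = n_total, prob = 0.5, lower.tail = FALSE)
}

#' Correlation and concordance structure between two sets of results
#'
#' Compares per-feature log fold changes between two differential results
#' (two contrasts on one layer, or two layers on one contrast): Spearman
#' rank correlation, the fraction of shared features with the same direction
#' of change (with its one-sided exact binomial P against 0.5), and the
#' fraction whose 95% confidence intervals intersect.
#'
#' @param diff_a,diff_b `diff_result` tibbles sharing features.
#' @return A one-row `concordance_report` tibble: `n_total`, `n_concordant`,
#'   `proportion`, `binomial_p`, `spearman_rho`, `rho_p`,
#'   `ci_overlap_fraction`.
#' @export
contrast_correlation <- function(diff_a, diff_b) {
  shared <- intersect(diff_a$feature, diff_b$feature)
  if (length(shared) < 3L) {
    abort("need >= 3 shared features", class = "triomix_config_error")
  }
  a <- diff_a[match(shared, diff_a$feature), ]
  b <- diff_b[match(shared, diff_b$feature), ]
  ct <- suppressWarnings(
    cor.test(a$logFC, b$logFC, method = "spearman", exact = FALSE))
  same <- sign(a$logFC) == sign(b$logFC) & a$logFC != 0
  n_conc <- sum(same)
  tibble(
    n_total = length(shared),
    n_concordant = n_conc,
    proportion = n_conc / length(shared),
    binomial_p = binomial_concordance(n_conc, length(shared)),
    spearman_rho = unname(ct$estimate),
    rho_p = ct$p.value,
    ci_overlap_fraction = mean(a$ci_lo <= b$ci_hi & b$ci_lo <= a$ci_hi)
  )
}

#' PCA of samples on a feature subset with a separation verdict
#'
#' Centred (unscaled) principal component analysis of the samples restricted
#' to `feature_subset` — typically the features significant in the
#' osteophytic-vs-low-grade comparison. The verdict is `"separated"` when a
#' threshold on PC1 classifies osteophytic vs articular (high + low) samples
#' without error, falling back to an LDA on the PC1-PC2 plane.
#'
#' @param layer An `omics_layer`.
#' @param feature_subset Character vector of feature IDs (>= 2).
#' @param n_pc Number of component scores to return (default 2).
#' @return A `pca_separation` tibble of per-sample scores (`sample_id`,
#'   `patient`, `grade`, `PC1`, `PC2`, ...) with attributes `separated`
#'   (logical) and `var_explained`.
#' @export
pca_separation <- function(layer, feature_subset, n_pc = 2) {
  stopifnot(inherits(layer, "omics_layer"))
  feature_subset <- intersect(feature_subset, rownames(layer$values))
  if (length(feature_subset) < 2L) {
    abort("feature subset must contain >= 2 features present in the layer",
          class = "triomix_config_error")
  }
  x <- t(layer$values[feature_subset, , drop = FALSE])
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(n_pc), drop = FALSE])
  out <- dplyr::bind_cols(layer$samples, scores)
  osteo <- layer$samples$grade == "osteophytic"
  sep1 <- max(pc$x[osteo, 1]) < min(pc$x[!osteo, 1]) ||
    min(pc$x[osteo, 1]) > max(pc$x[!osteo, 1])
  separated <- sep1
  if (!sep1 && ncol(pc$x) >= 2L) {
    fit <- MASS::lda(pc$x[, 1:2], grouping = factor(osteo))
    separated <- all(predict(fit)$class == factor(osteo))
  }
  class(out) <- c("pca_separation", class(out))
  attr(out, "separated") <- separated
  attr(out, "var_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  out
}
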