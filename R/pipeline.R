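#' Configuration of an end-to-end pipeline run
#'
#' Bundles the simulation (or input) configuration with the analysis
#' thresholds: the primary FDR (0.1%, the headline significance level) and
#' secondary FDR (5%, used for cross-contrast support), the DMR caller
#' parameters, and the enrichment parameters.
#'
#' @param sim A [sim_config()] describing the dataset to simulate, or a
#'   `sim_dataset` to analyse as-is.
#' @param primary_fdr,secondary_fdr FDR thresholds in (0, 1) with
#'   `primary_fdr <= secondary_fdr` (defaults 0.001 and 0.05).
#' @param dmr_lambda_bp,dmr_min_probes DMR caller parameters (defaults
#'   1000 bp, 2 probes).
#' @param enrich_n_rand Randomizations for the integrative FDR
#'   (default 1000).
#' @param per_layer_alpha,min_support_genes,min_support_layers Enrichment
#'   support-filter parameters.
#' @param beta_clip Clip bound applied before the beta-to-M transform.
#' @param seed Seed for the enrichment randomizations.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), primary_fdr = 0.001,
                       secondary_fdr = 0.05, dmr_lambda_bp = 1000,
                       dmr_min_probes = 2, enrich_n_rand = 1000,
                       per_layer_alpha = 0.05, min_support_genes = 5,
                       min_support_layers = 2, beta_clip = 1e-6,
                       seed = 1L) {
  check_number(primary_fdr, "primary_fdr", lower = 1e-12, upper = 1 - 1e-12)
  check_number(secondary_fdr, "secondary_fdr", lower = 1e-12, upper = 1 - 1e-12)
  if (primary_fdr > secondary_fdr) {
    config_error("'primary_fdr' must be <= 'secondary_fdr'")
  }
  stopifnot(inherits(sim, "sim_config") || inherits(sim, "sim_dataset"))
  structure(
    list(sim = sim, primary_fdr = primary_fdr, secondary_fdr = secondary_fdr,
         dmr_lambda_bp = dmr_lambda_bp, dmr_min_probes = dmr_min_probes,
         enrich_n_rand = enrich_n_rand, per_layer_alpha = per_layer_alpha,
         min_support_genes = min_support_genes,
         min_support_layers = min_support_layers,
         beta_clip = beta_clip, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full cross-omics pipeline
#'
#' Simulate (or take) a matched three-layer dataset, preprocess each layer,
#' run the paired differential analysis for every layer and contrast, call
#' DMRs and overlap them with genes, build the triple-significant gene list
#' with concordance statistics, compute the cross-contrast and cross-layer
#' correlation structure, check PCA separation, and run the integrative
#' gene-set enrichment.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV and the machine-readable summary as JSON.
#' @return A list of class `triomix_run` with elements `sim`, `diff`
#'   (list by layer then contrast), `dmr` and `dmr_genes` (by contrast),
#'   `triple`, `concordance`, `pca`, `enrichment`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- if (inherits(config$sim, "sim_dataset")) config$sim
         else generate_dataset(config$sim)

  meth <- beta_to_m(sim$layers$methylation, clip = config$beta_clip)
  protein <- normalize_protein(filter_complete(sim$layers$protein))
  rna <- sim$layers$rna
  layers <- list(methylation = meth, rna = rna, protein = protein)

  diff <- lapply(layers, function(ly) {
    lapply(CONTRASTS, function(ct) diff_paired(ly, ct))
  })

  dmr <- lapply(CONTRASTS, function(ct) {
    call_dmrs(diff$methylation[[ct]], sim$probe_annotation,
              lambda_bp = config$dmr_lambda_bp,
              min_probes = config$dmr_min_probes,
              probe_fdr = config$primary_fdr)
  })
  dmr_genes <- lapply(CONTRASTS, function(ct) {
    overlap_genes(dmr[[ct]], sim$gene_intervals,
                  diff$methylation[[ct]], sim$probe_annotation)
  })
  # DMR gene support in the secondary contrast is assessed at the
  # secondary FDR (region-level)
  dmr_secondary <- call_dmrs(diff$methylation$O_vs_H, sim$probe_annotation,
                             lambda_bp = config$dmr_lambda_bp,
                             min_probes = config$dmr_min_probes,
                             probe_fdr = config$secondary_fdr)
  dmr_genes_secondary <- overlap_genes(dmr_secondary, sim$gene_intervals,
                                       diff$methylation$O_vs_H,
                                       sim$probe_annotation)

  triple <- triple_overlap(
    diff$rna$O_vs_L, diff$protein$O_vs_L, dmr_genes$O_vs_L,
    fdr = config$primary_fdr,
    secondary = list(rna = diff$rna$O_vs_H, protein = diff$protein$O_vs_H,
                     dmr_genes = dmr_genes_secondary),
    secondary_fdr = config$secondary_fdr)

  concordance <- dplyr::bind_rows(
    rna_OvL_vs_HvL = contrast_correlation(diff$rna$O_vs_L, diff$rna$H_vs_L),
    rna_OvL_vs_OvH = contrast_correlation(diff$rna$O_vs_L, diff$rna$O_vs_H),
    protein_OvL_vs_HvL = contrast_correlation(diff$protein$O_vs_L,
                                              diff$protein$H_vs_L),
    protein_OvL_vs_OvH = contrast_correlation(diff$protein$O_vs_L,
                                              diff$protein$O_vs_H),
    rna_vs_protein_OvL = contrast_correlation(diff$rna$O_vs_L,
                                              diff$protein$O_vs_L),
    .id = "comparison")

  pca <- lapply(layers, function(ly) {
    lname <- ly$layer
    feats <- if (lname == "methylation") {
      unique(unlist(dmr$O_vs_L$probe_ids))
    } else {
      significant_features(diff[[lname]]$O_vs_L, config$primary_fdr)
    }
    if (length(feats) < 2L) return(NULL)
    pca_separation(ly, feats)
  })

  universes <- list(
    methylation = sort(unique(sim$probe_annotation$gene[
      nzchar(sim$probe_annotation$gene)])),
    rna = rownames(rna$values),
    protein = rownames(protein$values))
  sig_lists <- list(
    methylation = dmr_genes$O_vs_L$gene,
    rna = significant_features(diff$rna$O_vs_L, config$primary_fdr),
    protein = significant_features(diff$protein$O_vs_L, config$primary_fdr))
  enrichment <- enrich_integrative(
    sig_lists, universes, sim$gene_sets,
    n_rand = config$enrich_n_rand, seed = config$seed,
    per_layer_alpha = config$per_layer_alpha,
    min_support_genes = config$min_support_genes,
    min_support_layers = config$min_support_layers)

  summary <- run_summary(config, sim, diff, dmr, dmr_genes, triple,
                         concordance, pca, enrichment)
  run <- structure(
    list(sim = sim, layers = layers, diff = diff, dmr = dmr,
         dmr_genes = dmr_genes, triple = triple, concordance = concordance,
         pca = pca, enrichment = enrichment, summary = summary),
    class = "triomix_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

run_summary <- function(config, sim, diff, dmr, dmr_genes, triple,
                        concordance, pca, enrichment) {
  n_sig <- lapply(diff, function(by_ct) {
    lapply(by_ct, function(d) sum(d$q <= config$primary_fdr))
  })
  enriched <- enrichment$integrative_q <= config$secondary_fdr &
    enrichment$filtered_reason == "none"
  cfg <- config
  cfg$sim <- if (inherits(config$sim, "sim_dataset")) config$sim$config
             else config$sim
  list(
    n_significant_primary = n_sig,
    n_dmrs = lapply(dmr, nrow),
    n_dmr_genes = lapply(dmr_genes, nrow),
    n_triple_genes = nrow(triple),
    n_triple_concordant = sum(triple$rna_protein_concordant),
    concordance = concordance,
    pca_separated = lapply(pca, function(p) {
      if (is.null(p)) NA else attr(p, "separated")
    }),
    n_enriched_sets = sum(enriched),
    seeds = list(simulation = cfg$sim$seed, enrichment = config$seed),
    config_hash = rlang::hash(cfg)
  )
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (ly in names(run$diff)) {
    for (ct in names(run$diff[[ly]])) {
      readr::write_tsv(tidy(run$diff[[ly]][[ct]]),
                       file.path(out_dir, sprintf("diff_%s_%s.tsv", ly, ct)))
    }
  }
  for (ct in names(run$dmr)) {
    d <- run$dmr[[ct]]
    d$probe_ids <- vapply(d$probe_ids, paste, "", collapse = ",")
    readr::write_tsv(d, file.path(out_dir, sprintf("dmr_%s.tsv", ct)))
    g <- run$dmr_genes[[ct]]
    g$regions <- vapply(g$regions, paste, "", collapse = ",")
    readr::write_tsv(g, file.path(out_dir, sprintf("dmr_genes_%s.tsv", ct)))
  }
  readr::write_tsv(tidy_triple(run$triple),
                   file.path(out_dir, "triple_overlap.tsv"))
  readr::write_tsv(run$concordance, file.path(out_dir, "concordance.tsv"))
  readr::write_tsv(as_tibble(as.data.frame(run$enrichment)),
                   file.path(out_dir, "enrichment.tsv"))
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

tidy_triple <- function(triple) {
  out <- triple
  class(out) <- setdiff(class(out), "cross_omics_genes")
  out
}

#' @export
print.triomix_run <- function(x, ...) {
  s <- x$summary
  cat("<triomix_run>\n")
  cat(sprintf("  significant at primary FDR (O_vs_L): meth probes %d, rna %d, protein %d\n",
              s$n_significant_primary$methylation$O_vs_L,
              s$n_significant_primary$rna$O_vs_L,
              s$n_significant_primary$protein$O_vs_L))
  cat(sprintf("  DMRs (O_vs_L): %d over %d genes\n",
              s$n_dmrs$O_vs_L, s$n_dmr_genes$O_vs_L))
  cat(sprintf("  triple-significant genes: %d (%d RNA-protein concordant)\n",
              s$n_triple_genes, s$n_triple_concordant))
  cat(sprintf("  enriched gene sets passing filters: %d\n", s$n_enriched_sets))
  invisible(x)
}
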