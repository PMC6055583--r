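#' Call differentially methylated regions from probe-level results
#'
#' Probes significant at `probe_fdr` are sorted by position and merged into
#' maximal runs in which consecutive significant probes on the same
#' chromosome are at most `lambda_bp` apart; runs with fewer than
#' `min_probes` probes are discarded. Each region gets a Stouffer statistic
#' from its member probes: `z_i = qnorm(1 - p_i/2) * sign(logFC_i)` and
#' `region_p = 1 - pnorm(|sum(z_i)| / sqrt(n))`, so a region mixing
#' methylation directions can self-cancel (regions are built from
#' significant probes, so mixtures are rare). `region_q` is BH over regions.
#'
#' Coordinates are 1-based inclusive throughout.
#'
#' @param probe_results A `diff_result` (or tibble with `feature`, `logFC`,
#'   `p`, `q`) from the methylation layer.
#' @param annotation Probe annotation tibble (`probe_id`, `chrom`, `pos`,
#'   `gene`); every probe in `probe_results` must be present.
#' @param lambda_bp Maximum gap between consecutive significant probes
#'   within a region (default 1000).
#' @param min_probes Minimum significant probes per region (default 2).
#' @param probe_fdr Probe-level FDR threshold (default 0.001).
#' @return A `dmr_regions` tibble with columns `chrom`, `start`, `end`,
#'   `n_probes`, `probe_ids` (list), `region_p`, `region_q`.
#' @export
call_dmrs <- function(probe_results, annotation, lambda_bp = 1000,
                      min_probes = 2, probe_fdr = 0.001) {
  stopifnot(all(c("feature", "logFC", "p", "q") %in% names(probe_results)))
  check_number(lambda_bp, "lambda_bp", lower = 1)
  check_number(min_probes, "min_probes", lower = 1, integer = TRUE)
  idx <- match(probe_results$feature, annotation$probe_id)
  if (anyNA(idx)) {
    abort(sprintf("probe(s) missing from annotation: %s",
                  paste(head(probe_results$feature[is.na(idx)], 5L),
                        collapse = ", ")),
          class = "triomix_annotation_error")
  }
  sig <- tibble(
    probe_id = probe_results$feature,
    chrom = annotation$chrom[idx],
    pos = annotation$pos[idx],
    logFC = probe_results$logFC,
    p = probe_results$p
  )[probe_results$q <= probe_fdr, ]
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_probes = integer(), probe_ids = list(),
                  region_p = double(), region_q = double())
  class(empty) <- c("dmr_regions", class(empty))
  if (nrow(sig) < min_probes) return(empty)

  sig <- sig[order(sig$chrom, sig$pos), ]
  new_run <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                 diff(sig$pos) > lambda_bp)
  sig$run <- cumsum(new_run)

  regions <- sig |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos), end = max(.data$pos),
      n_probes = dplyr::n(),
      probe_ids = list(.data$probe_id),
      region_p = stouffer_region_p(.data$p, .data$logFC),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_probes >= min_probes) |>
    dplyr::select(-"run")
  if (nrow(regions) == 0L) return(empty)
  regions$region_q <- bh_adjust(regions$region_p)
  class(regions) <- c("dmr_regions", class(regions))
  regions
}

# signed Stouffer combination: one-sided normal tail on |mean z| * sqrt(n)
stouffer_region_p <- function(p, logFC) {
  z <- qnorm(1 - p / 2) * sign(logFC)
  pnorm(abs(sum(z)) / sqrt(length(z)), lower.tail = FALSE)
}

#' Overlap DMRs with gene intervals and summarise per-gene DMPs
#'
#' A region overlaps a gene iff the 1-based inclusive intervals share at
#' least one base. For each overlapped gene, the differentially methylated
#' probes (DMPs, i.e. probes significant at the caller's threshold) lying
#' inside overlapping regions *and* annotated to that gene are counted, and
#' `prop_pos_beta` is the proportion of those DMPs with increased
#' methylation (positive logFC) in the first-named tissue.
#'
#' @param regions A `dmr_regions` tibble from [call_dmrs()].
#' @param gene_intervals Tibble with `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param probe_results The probe-level `diff_result` used for the calls.
#' @param annotation Probe annotation tibble (`probe_id`, `chrom`, `pos`,
#'   `gene`).
#' @return A tibble with one row per overlapped gene: `gene`,
#'   `n_dmps_in_dmrs`, `prop_pos_beta`, `regions` (list of region row
#'   indices).
#' @export
overlap_genes <- function(regions, gene_intervals, probe_results, annotation) {
  if (nrow(regions) == 0L) {
    return(tibble(gene = character(), n_dmps_in_dmrs = integer(),
                  prop_pos_beta = double(), regions = list()))
  }
  # overlap per chromosome, keeping original row indices
  reg_by_chr <- split(seq_len(nrow(regions)), regions$chrom)
  gene_by_chr <- split(seq_len(nrow(gene_intervals)), gene_intervals$chrom)
  chroms_r <- names(reg_by_chr)
  pairs <- purrr::map_dfr(seq_along(chroms_r), function(ci) {
    chr <- chroms_r[ci]
    if (!chr %in% names(gene_by_chr)) return(tibble())
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(regions$start[reg_by_chr[[chr]]],
                       regions$end[reg_by_chr[[chr]]]),
      IRanges::IRanges(gene_intervals$start[gene_by_chr[[chr]]],
                       gene_intervals$end[gene_by_chr[[chr]]]))
    tibble(region = reg_by_chr[[chr]][S4Vectors::queryHits(ov)],
           gene_row = gene_by_chr[[chr]][S4Vectors::subjectHits(ov)])
  })
  if (nrow(pairs) == 0L) {
    return(tibble(gene = character(), n_dmps_in_dmrs = integer(),
                  prop_pos_beta = double(), regions = list()))
  }
  pairs$gene <- gene_intervals$gene[pairs$gene_row]

  # per-gene DMP summaries: probes of overlapping regions annotated to gene
  ann_idx <- match(probe_results$feature, annotation$probe_id)
  probe_gene <- annotation$gene[ann_idx]
  probe_fc <- setNames(probe_results$logFC, probe_results$feature)
  summaries <- pairs |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_dmps_in_dmrs = {
        ids <- unique(unlist(regions$probe_ids[.data$region]))
        sum(probe_gene[match(ids, probe_results$feature)] == .data$gene[1],
            na.rm = TRUE)
      },
      prop_pos_beta = {
        ids <- unique(unlist(regions$probe_ids[.data$region]))
        ids <- ids[probe_gene[match(ids, probe_results$feature)] == .data$gene[1]]
        ids <- ids[!is.na(ids)]
        if (length(ids)) mean(probe_fc[ids] > 0) else NA_real_
      },
      regions = list(sort(unique(.data$region))),
      .groups = "drop"
    )
  summaries
}
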