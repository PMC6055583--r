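#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields `name`,
#' `description`, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character member vectors, with the descriptions in
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    config_error(sprintf("GMT line(s) with < 3 fields: %s",
                         paste(which(bad)[1:min(3, sum(bad))], collapse = ", ")))
  }
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character member vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (defaults
#'   to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' One-sided hypergeometric gene-set enrichment
#'
#' `N` is the overlap of the significant list with the term, `FC` the
#' fold-change enrichment `N / expected` with
#' `expected = |sig| * |term| / |universe|`, and `p = P(X >= N)` under the
#' hypergeometric null (exact tail).
#'
#' @param sig_genes Character vector of significant genes (subset of
#'   `universe`).
#' @param term_genes Character vector of term members (subset of
#'   `universe`).
#' @param universe Character vector of testable genes.
#' @return A one-row tibble with `N`, `FC`, `p` (`FC` is `NA` when the
#'   expected overlap is zero).
#' @export
hypergeom_enrich <- function(sig_genes, term_genes, universe) {
  if (length(universe) == 0L) config_error("empty universe")
  sig <- intersect(sig_genes, universe)
  term <- intersect(term_genes, universe)
  n_u <- length(universe)
  n <- length(intersect(sig, term))
  expected <- length(sig) * length(term) / n_u
  tibble(
    N = n,
    FC = if (expected > 0) n / expected else NA_real_,
    p = phyper(n - 1, m = length(term), n = n_u - length(term),
               k = length(sig), lower.tail = FALSE)
  )
}

#' Combine per-layer enrichment P-values (Fisher's method)
#'
#' `X^2 = -2 * sum(log p)` referred to a chi-square distribution with
#' `2 * length(p)` degrees of freedom (6 df for three layers). The
#' chi-square reference P is used for ranking; final inference in
#' [randomization_fdr()] uses the randomization null, which makes the
#' result robust to the choice of combination rule. Zero P-values are
#' clipped to `p_floor`.
#'
#' @param p Numeric vector of per-layer P-values in `(0, 1]`.
#' @param p_floor Floor applied to zero/underflowed values (default 1e-300).
#' @return A list with `combined_stat` and `combined_p`.
#' @export
combine_levels <- function(p, p_floor = 1e-300) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    config_error("p-values must be in [0, 1] with no NA")
  }
  p <- pmax(p, p_floor)
  x2 <- -2 * sum(log(p))
  list(combined_stat = x2,
       combined_p = pchisq(x2, df = 2 * length(p), lower.tail = FALSE))
}

# vectorized internals: set-by-gene membership matrix over one universe
membership_matrix <- function(gene_sets, universe) {
  m <- matrix(0, nrow = length(gene_sets), ncol = length(universe),
              dimnames = list(names(gene_sets), universe))
  for (i in seq_along(gene_sets)) {
    m[i, universe %in% gene_sets[[i]]] <- 1
  }
  m
}

hyper_p_vec <- function(n, term_sizes, n_universe, n_sig) {
  phyper(as.vector(n) - 1, m = rep_len(term_sizes, length(n)),
         n = n_universe - rep_len(term_sizes, length(n)),
         k = n_sig, lower.tail = FALSE)
}

#' Integrative cross-layer gene-set enrichment
#'
#' For each gene set and each omics layer, computes the one-sided
#' hypergeometric enrichment of that layer's significant genes within the
#' layer's testable universe, combines the three P-values with Fisher's
#' method, assigns an integrative FDR by label randomization
#' ([randomization_fdr()]), and applies the multi-layer support filters
#' ([support_filter()]).
#'
#' @param sig_lists Named list (`methylation`, `rna`, `protein`) of
#'   significant gene vectors. For methylation, the genes overlapped by
#'   DMRs at the configured FDR.
#' @param universes Named list of per-layer testable gene vectors.
#' @param gene_sets Named list of set member vectors (e.g. from
#'   [read_gmt()]).
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Integer seed for the randomizations.
#' @param per_layer_alpha Per-layer enrichment threshold for the support
#'   filter (default 0.05).
#' @param min_support_genes,min_support_layers Support-filter parameters
#'   (defaults 5 genes on at least 2 layers).
#' @return An `enrichment_records` tibble, one row per set, with per-layer
#'   `N_*`, `FC_*`, `p_*` columns, `combined_stat`, `combined_p`,
#'   `integrative_q`, `filtered_reason`.
#' @export
enrich_integrative <- function(sig_lists, universes, gene_sets,
                               n_rand = 1000, seed = 1L,
                               per_layer_alpha = 0.05,
                               min_support_genes = 5,
                               min_support_layers = 2) {
  stopifnot(all(LAYERS %in% names(sig_lists)),
            all(LAYERS %in% names(universes)))
  drop <- vapply(gene_sets,
                 function(g) all(vapply(universes[LAYERS],
                                        function(u) !any(g %in% u), TRUE)),
                 TRUE)
  if (any(drop)) {
    warn(sprintf("dropping %d gene set(s) with no member in any universe",
                 sum(drop)))
    gene_sets <- gene_sets[!drop]
  }
  records <- tibble(set = names(gene_sets),
                    set_size = lengths(gene_sets))
  for (ly in LAYERS) {
    u <- universes[[ly]]
    res <- purrr::map_dfr(gene_sets, hypergeom_enrich,
                          sig_genes = sig_lists[[ly]], universe = u)
    records[[paste0("N_", ly)]] <- res$N
    records[[paste0("FC_", ly)]] <- res$FC
    records[[paste0("p_", ly)]] <- res$p
  }
  comb <- purrr::pmap(
    list(records$p_methylation, records$p_rna, records$p_protein),
    function(a, b, c) combine_levels(c(a, b, c)))
  records$combined_stat <- vapply(comb, `[[`, 0, "combined_stat")
  records$combined_p <- vapply(comb, `[[`, 0, "combined_p")
  records$integrative_q <- randomization_fdr(records, sig_lists, universes,
                                             gene_sets, n_rand = n_rand,
                                             seed = seed)
  records <- support_filter(records, per_layer_alpha = per_layer_alpha,
                            min_support_genes = min_support_genes,
                            min_support_layers = min_support_layers)
  class(records) <- c("enrichment_records", class(records))
  records
}

#' Randomization-based integrative FDR
#'
#' For each randomization the three per-layer significant-gene labels are
#' independently re-drawn uniformly from the layer's universe (preserving
#' the per-layer significant-list sizes) and all combined statistics are
#' recomputed. The integrative FDR of a record with combined P-value `c` is
#' the mean null count of sets with combined P at most `c` divided by the
#' observed count, clipped to `[0, 1]` and monotonized in `c`.
#'
#' @param records Tibble of observed records with a `combined_p` column
#'   (one row per gene set, in `gene_sets` order).
#' @param sig_lists,universes,gene_sets As in [enrich_integrative()].
#' @param n_rand Number of randomizations (>= 100).
#' @param seed Integer seed.
#' @return Numeric vector of integrative FDR values, aligned with
#'   `records`.
#' @export
randomization_fdr <- function(records, sig_lists, universes, gene_sets,
                              n_rand = 1000, seed = 1L) {
  check_number(n_rand, "n_rand", lower = 100, integer = TRUE)
  k_sets <- length(gene_sets)
  stopifnot(nrow(records) == k_sets)
  null_comb <- withr::with_seed(seed, {
    x2 <- matrix(0, nrow = k_sets, ncol = n_rand)
    for (ly in LAYERS) {
      u <- universes[[ly]]
      g <- length(u)
      n_sig <- length(intersect(sig_lists[[ly]], u))
      m <- membership_matrix(gene_sets, u)
      term_sizes <- rowSums(m)
      s <- matrix(0, nrow = g, ncol = n_rand)
      for (b in seq_len(n_rand)) {
        if (n_sig > 0) s[sample.int(g, n_sig), b] <- 1
      }
      n_null <- m %*% s
      p_null <- matrix(pmax(hyper_p_vec(n_null, term_sizes, g, n_sig), 1e-300),
                       nrow = k_sets)
      x2 <- x2 - 2 * log(p_null)
    }
    pchisq(x2, df = 6, lower.tail = FALSE)
  })
  obs <- records$combined_p
  ord <- order(obs)
  null_sorted <- sort(as.vector(null_comb))
  # counts of null/observed combined_p <= each observed value
  n_null_le <- findInterval(obs[ord], null_sorted)
  n_obs_le <- vapply(obs[ord], function(c) sum(obs <= c), 0L)
  raw_q <- pmin(1, (n_null_le / n_rand) / pmax(n_obs_le, 1L))
  q_sorted <- rev(cummin(rev(raw_q)))
  q <- numeric(k_sets)
  q[ord] <- q_sorted
  q
}

#' Multi-layer support filter for enrichment records
#'
#' A record passes when the per-layer enrichment P is below
#' `per_layer_alpha` on at least `min_support_layers` layers *and* at least
#' `min_support_genes` genes contribute to the enrichment (overlap `N`) on
#' at least `min_support_layers` layers. Otherwise `filtered_reason` is
#' `"single-layer-only"` (too few nominally enriched layers) or
#' `"insufficient-support"` (too few contributing genes).
#'
#' @param records Tibble with per-layer `p_*` and `N_*` columns.
#' @param per_layer_alpha,min_support_genes,min_support_layers Filter
#'   parameters (defaults 0.05, 5, 2).
#' @return `records` with a `filtered_reason` column
#'   (`"none"` for passing records).
#' @export
support_filter <- function(records, per_layer_alpha = 0.05,
                           min_support_genes = 5, min_support_layers = 2) {
  p_mat <- as.matrix(records[, paste0("p_", LAYERS)])
  n_mat <- as.matrix(records[, paste0("N_", LAYERS)])
  enough_layers <- rowSums(p_mat < per_layer_alpha) >= min_support_layers
  enough_genes <- rowSums(n_mat >= min_support_genes) >= min_support_layers
  records$filtered_reason <- dplyr::case_when(
    !enough_layers ~ "single-layer-only",
    !enough_genes ~ "insufficient-support",
    TRUE ~ "none"
  )
  records
}
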