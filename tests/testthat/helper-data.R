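# small paired layers and datasets built in code for the tests

paired_samples <- function(n_patients, grades = c("low", "high", "osteophytic")) {
  s <- expand.grid(grade = grades, patient = sprintf("P%d", seq_len(n_patients)),
                   stringsAsFactors = FALSE)[, 2:1]
  s$sample_id <- paste0(s$patient, "_", s$grade)
  tibble::as_tibble(s)
}

# layer whose osteophytic-minus-low paired differences are exactly `diffs`
# (one feature per row of `diffs`)
layer_from_diffs <- function(diffs, layer = "rna") {
  diffs <- rbind(diffs)
  n_pat <- ncol(diffs)
  s <- paired_samples(n_pat)
  vals <- matrix(0, nrow(diffs), nrow(s),
                 dimnames = list(sprintf("f%d", seq_len(nrow(diffs))),
                                 s$sample_id))
  vals[, s$grade == "osteophytic"] <- diffs
  omics_layer(vals, layer, s)
}

random_layer <- function(n_features, n_patients = 5, layer = "rna", sd = 1) {
  s <- paired_samples(n_patients)
  vals <- matrix(rnorm(n_features * nrow(s), sd = sd), n_features,
                 dimnames = list(sprintf("f%03d", seq_len(n_features)),
                                 s$sample_id))
  omics_layer(vals, layer, s)
}

quick_sim_config <- function(seed = 1, ...) {
  args <- list(n_genes = 300, n_proteins = 200, probes_per_gene = 5,
               n_decoy_sets = 20, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# direct step-up BH oracle (independent of stats::p.adjust)
bh_stepup_rejections <- function(p, alpha) {
  n <- length(p)
  ord <- order(p)
  k <- which(p[ord] <= alpha * seq_len(n) / n)
  if (!length(k)) return(integer(0))
  sort(ord[seq_len(max(k))])
}

# exact hypergeometric upper tail by enumeration of all draws (universe <= 12)
hyper_tail_enum <- function(universe, term, sig) {
  draws <- utils::combn(length(universe), length(sig))
  n_obs <- length(intersect(sig, term))
  term_idx <- which(universe %in% term)
  tails <- apply(draws, 2, function(d) sum(d %in% term_idx) >= n_obs)
  mean(tails)
}
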