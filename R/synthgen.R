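#' Simulation configuration for matched three-grade multi-omics data
#'
#' Defines the generative conditions for a paired cartilage-style design:
#' `n_patients` patients each contribute one sample per tissue grade
#' (low-grade, high-grade, osteophytic) on three omics layers (methylation
#' probes, RNA, protein). A fraction of genes carries true
#' osteophytic-vs-low-grade effects; high-grade means sit between the
#' extremes so that high-vs-low effects are attenuated versions of the
#' osteophytic-vs-low effects and osteophytic-vs-high effects are nearly as
#' large (directionally aligned throughout).
#'
#' Effect sizes for affected genes are `effect_scale_ovl * sign(x) * (0.5 + |x|)`
#' with `x` standard normal, i.e. a magnitude floor of half the scale keeps
#' planted effects detectable; RNA and protein share a latent factor with
#' correlation `rna_protein_corr`; the methylation effect direction is drawn
#' independently of expression (both hyper- and hypomethylation occur among
#' up- and down-regulated genes) and is applied coherently to every probe of
#' the gene.
#'
#' @param n_patients Number of patients (default 9, the study design).
#' @param n_genes Number of genes on the RNA layer (default 2000, a
#'   scaled-down stand-in for the ~14k-gene transcriptome).
#' @param n_proteins Number of genes also quantified on the protein layer
#'   (random subset of genes; default 1200).
#' @param n_probes Total methylation probe count; `NULL` (default) derives it
#'   from `probes_per_gene` draws, otherwise probes are assigned to genes
#'   uniformly at random.
#' @param probes_per_gene Mean probes per gene (count drawn as
#'   `1 + Poisson(probes_per_gene - 1)`; default 10).
#' @param frac_affected_genes Fraction of genes with true effects (default 0.2).
#' @param effect_scale_ovl Osteophytic-vs-low-grade effect scale in
#'   within-sample SD units (default 2).
#' @param effect_ratio_ovh Multiplier in (0, 1] for osteophytic-vs-high
#'   effects relative to osteophytic-vs-low (default 0.9).
#' @param effect_ratio_hvl Multiplier in (0, 1) for high-vs-low effects
#'   (default 0.3; attenuation of the articular contrast).
#' @param rna_protein_corr Target correlation of RNA and protein effects
#'   (default 0.6).
#' @param noise_sd Named numeric: typical residual SD per layer
#'   (methylation M-value, log2 RNA, log2 protein).
#' @param var_prior_df Degrees of freedom of the scaled inverse chi-square
#'   from which per-feature residual variances are drawn around
#'   `noise_sd^2` (default 20); finite values give the variance
#'   heterogeneity seen in real omics data.
#' @param patient_sd SD of the per-gene patient random intercept (default 0.5).
#' @param planted_sets List describing gene sets planted with affected
#'   members; each element a list with `name`, `size` (or explicit `members`)
#'   and `affected_frac`. `NULL` (default) plants 5 sets of 40 genes with
#'   affected fraction 0.8.
#' @param n_decoy_sets Number of random decoy gene sets (default 95).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 9, n_genes = 2000, n_proteins = 1200,
                       n_probes = NULL, probes_per_gene = 10,
                       frac_affected_genes = 0.2,
                       effect_scale_ovl = 2,
                       effect_ratio_ovh = 0.9, effect_ratio_hvl = 0.3,
                       rna_protein_corr = 0.6,
                       noise_sd = c(methylation = 0.5, rna = 0.6, protein = 0.8),
                       var_prior_df = 20,
                       patient_sd = 0.5,
                       planted_sets = NULL, n_decoy_sets = 95,
                       seed = 1L) {
  check_number(n_patients, "n_patients", lower = 2, integer = TRUE)
  check_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_number(n_proteins, "n_proteins", lower = 1, upper = n_genes, integer = TRUE)
  if (!is.null(n_probes)) check_number(n_probes, "n_probes", lower = 1, integer = TRUE)
  check_number(probes_per_gene, "probes_per_gene", lower = 1)
  check_number(frac_affected_genes, "frac_affected_genes", lower = 0, upper = 1)
  check_number(effect_scale_ovl, "effect_scale_ovl", lower = 0)
  check_number(effect_ratio_ovh, "effect_ratio_ovh", lower = 1e-12, upper = 1)
  if (effect_ratio_hvl >= 1) config_error("field 'effect_ratio_hvl' must be < 1")
  check_number(effect_ratio_hvl, "effect_ratio_hvl", lower = 0, upper = 1)
  check_number(rna_protein_corr, "rna_protein_corr", lower = 0, upper = 1)
  if (!all(LAYERS %in% names(noise_sd)) || any(noise_sd[LAYERS] <= 0)) {
    config_error("field 'noise_sd' must be positive and named for methylation/rna/protein")
  }
  check_number(var_prior_df, "var_prior_df", lower = 2 + 1e-9)
  check_number(patient_sd, "patient_sd", lower = 0)
  check_number(n_decoy_sets, "n_decoy_sets", lower = 0, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(n_patients = n_patients, n_genes = n_genes, n_proteins = n_proteins,
         n_probes = n_probes, probes_per_gene = probes_per_gene,
         frac_affected_genes = frac_affected_genes,
         effect_scale_ovl = effect_scale_ovl,
         effect_ratio_ovh = effect_ratio_ovh,
         effect_ratio_hvl = effect_ratio_hvl,
         rna_protein_corr = rna_protein_corr,
         noise_sd = noise_sd[LAYERS], var_prior_df = var_prior_df,
         patient_sd = patient_sd,
         planted_sets = planted_sets, n_decoy_sets = n_decoy_sets,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# signed magnitude-floored effect transform; strictly increasing in x
effect_transform <- function(x, scale) scale * sign(x) * (0.5 + abs(x))

# fraction of the OvL effect placed on the high-grade mean; both ratio
# parameters position high-grade between low and osteophytic (group-mean
# differences are additive, so the two ratios are reconciled symmetrically)
high_frac <- function(config) {
  (1 - config$effect_ratio_ovh + config$effect_ratio_hvl) / 2
}

#' Generate a matched three-layer multi-omics dataset with ground truth
#'
#' Simulates methylation (beta values), RNA (log2 expression) and protein
#' (raw abundances, pre-normalization) layers for the paired three-grade
#' design described in [sim_config()], together with the probe annotation,
#' gene intervals, a gene-set collection with planted enriched sets, and a
#' ground-truth table of true per-layer, per-contrast effects.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `layers` (named list
#'   of [omics_layer()]: methylation, rna, protein), `probe_annotation`
#'   (tibble: probe_id, chrom, pos, gene), `gene_intervals` (tibble: gene,
#'   chrom, start, end; 1-based inclusive), `gene_sets` (named list of member
#'   vectors), `set_info` (tibble: set, planted), `truth` (tibble of true
#'   effects per gene) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  n_g <- config$n_genes
  n_pat <- config$n_patients
  genes <- sprintf("G%05d", seq_len(n_g))

  # genes tiled on one synthetic chromosome: 2 kb probe-dense bodies,
  # 10 kb pitch so DMRs never merge across genes at the default lambda
  gene_start <- (seq_len(n_g) - 1L) * 10000L + 1L
  gene_intervals <- tibble(gene = genes, chrom = "chr1",
                           start = gene_start, end = gene_start + 1999L)

  protein_genes <- sort(sample(genes, config$n_proteins))
  n_aff <- round(config$frac_affected_genes * n_g)
  affected <- sort(sample(genes, n_aff))
  is_aff <- genes %in% affected

  # correlated latent effects: shared factor gives corr = rna_protein_corr
  r <- config$rna_protein_corr
  z <- rnorm(n_g)
  x_rna  <- sqrt(r) * z + sqrt(1 - r) * rnorm(n_g)
  x_prot <- sqrt(r) * z + sqrt(1 - r) * rnorm(n_g)
  x_meth <- rnorm(n_g)  # direction independent of expression

  sc <- config$effect_scale_ovl
  d_rna  <- ifelse(is_aff, effect_transform(x_rna, sc), 0)
  d_prot <- ifelse(is_aff, effect_transform(x_prot, sc), 0)
  d_meth <- ifelse(is_aff, effect_transform(x_meth, sc), 0)

  hf <- high_frac(config)
  in_prot <- genes %in% protein_genes
  truth <- tibble(
    gene = genes, affected = is_aff, in_protein = in_prot,
    rna_ovl = d_rna, rna_hvl = hf * d_rna, rna_ovh = (1 - hf) * d_rna,
    protein_ovl = ifelse(in_prot, d_prot, NA_real_),
    protein_hvl = ifelse(in_prot, hf * d_prot, NA_real_),
    protein_ovh = ifelse(in_prot, (1 - hf) * d_prot, NA_real_),
    meth_ovl = d_meth, meth_hvl = hf * d_meth, meth_ovh = (1 - hf) * d_meth
  )

  samples <- tibble(
    patient = rep(sprintf("P%d", seq_len(n_pat)), each = 3L),
    grade = rep(GRADES, times = n_pat)
  )
  samples$sample_id <- paste0(samples$patient, "_", samples$grade)
  grade_mult <- c(low = 0, high = hf, osteophytic = 1)[samples$grade]
  pat_idx <- rep(seq_len(n_pat), each = 3L)
  n_s <- nrow(samples)

  build_signal <- function(delta, baseline, noise) {
    k <- length(baseline)
    pat <- matrix(rnorm(k * n_pat, sd = config$patient_sd), ncol = n_pat)
    # per-feature residual SDs: scaled inverse chi-square around noise^2,
    # the variance heterogeneity the moderated t models
    sd_feat <- noise * sqrt(config$var_prior_df /
                              stats::rchisq(k, config$var_prior_df))
    baseline + pat[, pat_idx, drop = FALSE] +
      outer(delta, grade_mult) +
      matrix(rnorm(k * n_s), ncol = n_s) * sd_feat
  }

  # RNA: log2 expression, emitted already normalized
  rna_vals <- build_signal(d_rna, rnorm(n_g, 6, 2), config$noise_sd[["rna"]])
  dimnames(rna_vals) <- list(genes, samples$sample_id)
  rna <- omics_layer(rna_vals, "rna", samples)

  # protein: log2 signal re-exponentiated and scaled by a per-sample depth
  # factor, so sum normalization is a real step downstream
  pi <- match(protein_genes, genes)
  prot_log <- build_signal(d_prot[pi], rnorm(length(pi), 4, 1.5),
                           config$noise_sd[["protein"]])
  depth <- exp(rnorm(n_s, 0, 0.2))
  prot_vals <- 2^prot_log * rep(depth, each = length(pi))
  dimnames(prot_vals) <- list(protein_genes, samples$sample_id)
  protein <- omics_layer(prot_vals, "protein", samples)

  # methylation: per-probe M-values with the gene's coherent effect,
  # reported as beta = 2^M / (1 + 2^M)
  if (is.null(config$n_probes)) {
    n_per_gene <- 1L + rpois(n_g, config$probes_per_gene - 1)
  } else {
    n_per_gene <- as.integer(table(factor(sample.int(n_g, config$n_probes,
                                                     replace = TRUE),
                                          levels = seq_len(n_g))))
  }
  probe_gene_idx <- rep(seq_len(n_g), times = n_per_gene)
  n_pr <- length(probe_gene_idx)
  offsets <- unlist(lapply(n_per_gene, function(k) sort(sample.int(2000L, k))),
                    use.names = FALSE)
  probe_annotation <- tibble(
    probe_id = sprintf("cg%06d", seq_len(n_pr)),
    chrom = "chr1",
    pos = gene_start[probe_gene_idx] + offsets - 1L,
    gene = genes[probe_gene_idx]
  )
  m_vals <- build_signal(d_meth[probe_gene_idx], rnorm(n_pr, 0, 2),
                         config$noise_sd[["methylation"]])
  beta_vals <- 2^m_vals / (1 + 2^m_vals)
  dimnames(beta_vals) <- list(probe_annotation$probe_id, samples$sample_id)
  methylation <- omics_layer(beta_vals, "methylation", samples, is_beta = TRUE)

  gs <- build_gene_sets(config, genes, affected)

  structure(
    list(layers = list(methylation = methylation, rna = rna, protein = protein),
         probe_annotation = probe_annotation, gene_intervals = gene_intervals,
         gene_sets = gs$sets, set_info = gs$info, truth = truth,
         config = config),
    class = "sim_dataset"
  )
}

build_gene_sets <- function(config, genes, affected) {
  planted <- config$planted_sets
  if (is.null(planted)) {
    planted <- lapply(seq_len(5L), function(i) {
      list(name = sprintf("planted_%02d", i), size = 40L, affected_frac = 0.8)
    })
  }
  unaffected <- setdiff(genes, affected)
  sets <- list()
  for (ps in planted) {
    if (!is.null(ps$members)) {
      sets[[ps$name]] <- ps$members
      next
    }
    k_aff <- min(round(ps$affected_frac * ps$size), length(affected))
    sets[[ps$name]] <- sample(c(
      sample(affected, k_aff),
      sample(unaffected, ps$size - k_aff)
    ))
  }
  n_planted <- length(sets)
  if (config$n_decoy_sets > 0) {
    sizes <- sample(20:60, config$n_decoy_sets, replace = TRUE)
    for (i in seq_len(config$n_decoy_sets)) {
      sets[[sprintf("decoy_%03d", i)]] <- sample(genes, sizes[i])
    }
  }
  list(sets = sets,
       info = tibble(set = names(sets),
                     planted = seq_along(sets) <= n_planted))
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d patients x 3 grades; %d genes, %d proteins, %d probes; %d gene sets (%d planted)\n",
    x$config$n_patients, x$config$n_genes, x$config$n_proteins,
    nrow(x$probe_annotation), length(x$gene_sets), sum(x$set_info$planted)))
  invisible(x)
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Layers are written as TSV (see [write_layer_tsv()]), the probe annotation
#' and gene intervals as BED-like TSV (0-based half-open coordinates on
#' export), gene sets as GMT, and the ground truth as TSV.
#'
#' @param sim A `sim_dataset` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(sim$layers)) {
    write_layer_tsv(sim$layers[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  ann <- sim$probe_annotation
  readr::write_tsv(
    tibble(chrom = ann$chrom, start = ann$pos - 1L, end = ann$pos,
           probe_id = ann$probe_id, gene = ann$gene),
    file.path(dir, "probes.bed"))
  gi <- sim$gene_intervals
  readr::write_tsv(
    tibble(chrom = gi$chrom, start = gi$start - 1L, end = gi$end,
           gene = gi$gene),
    file.path(dir, "genes.bed"))
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a BED-like probe annotation written by [write_simulation()]
#'
#' Converts the exported 0-based half-open coordinates back to the 1-based
#' positions used internally.
#'
#' @param path File path.
#' @return A tibble with columns `probe_id`, `chrom`, `pos`, `gene`.
#' @export
read_probe_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble(probe_id = df$probe_id, chrom = df$chrom,
         pos = df$end, gene = df$gene)
}
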