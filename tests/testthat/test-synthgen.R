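test_that("generation is byte-identical under a fixed seed", {
  cfg <- quick_sim_config(seed = 7)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$layers$rna$values, b$layers$rna$values)
  expect_identical(a$layers$methylation$values, b$layers$methylation$values)
  expect_identical(a$layers$protein$values, b$layers$protein$values)
  expect_identical(a$probe_annotation, b$probe_annotation)
  expect_identical(a$gene_sets, b$gene_sets)
  expect_identical(a$truth, b$truth)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(frac_affected_genes = 1.2), "frac_affected_genes",
               class = "triomix_config_error")
  expect_error(sim_config(n_proteins = 5000, n_genes = 100), "n_proteins",
               class = "triomix_config_error")
  expect_error(sim_config(effect_ratio_hvl = 1), "effect_ratio_hvl",
               class = "triomix_config_error")
  expect_error(sim_config(n_patients = 0), "n_patients",
               class = "triomix_config_error")
})

test_that("ground truth separates affected from unaffected genes", {
  sim <- generate_dataset(quick_sim_config(seed = 2))
  tr <- sim$truth
  aff <- tr[tr$affected, ]
  expect_true(all(aff$rna_ovl != 0))
  expect_true(all(aff$meth_ovl != 0))
  expect_true(all(abs(aff$rna_ovl) >= 0.5 * sim$config$effect_scale_ovl))
  un <- tr[!tr$affected, ]
  expect_true(all(un$rna_ovl == 0 & un$meth_ovl == 0))
  expect_true(all(un$protein_ovl[un$in_protein] == 0))
  # attenuation structure: |HvL| < |OvH| <= |OvL| for affected genes
  expect_true(all(abs(aff$rna_hvl) < abs(aff$rna_ovl)))
  expect_true(all(abs(aff$rna_ovh) <= abs(aff$rna_ovl)))
})

test_that("layers respect the paired design and value domains", {
  sim <- generate_dataset(quick_sim_config(seed = 3))
  b <- sim$layers$methylation$values
  expect_true(all(b > 0 & b < 1))
  expect_true(sim$layers$methylation$is_beta)
  expect_true(all(sim$layers$protein$values >= 0))
  for (ly in sim$layers) {
    tab <- table(ly$samples$patient, ly$samples$grade)
    expect_true(all(tab == 1L))
  }
  # probes fall inside their gene's body
  ann <- dplyr::left_join(sim$probe_annotation, sim$gene_intervals,
                          by = "gene")
  expect_true(all(ann$pos >= ann$start & ann$pos <= ann$end))
  expect_true(all(rownames(sim$layers$protein$values) %in%
                    rownames(sim$layers$rna$values)))
})

test_that("a null configuration yields no affected genes and calibrated raw p-values", {
  sim <- generate_dataset(quick_sim_config(seed = 4, n_genes = 2000,
                                           frac_affected_genes = 0))
  expect_identical(sum(sim$truth$affected), 0L)
  d <- diff_paired(sim$layers$rna, "O_vs_L")
  expect_gt(mean(d$p < 0.05), 0.03)
  expect_lt(mean(d$p < 0.05), 0.07)
})

test_that("estimated cross-contrast correlation matches an independent simulation oracle", {
  cfg <- sim_config(n_genes = 2000, n_proteins = 1200,
                    frac_affected_genes = 0.2, effect_ratio_hvl = 0.3,
                    probes_per_gene = 2, seed = 9)
  sim <- generate_dataset(cfg)
  ovl <- diff_paired(sim$layers$rna, "O_vs_L")
  hvl <- diff_paired(sim$layers$rna, "H_vs_L")
  rho_pipeline <- contrast_correlation(ovl, hvl)$spearman_rho

  # Monte-Carlo oracle: simulate estimated logFC pairs for the same
  # generative model directly, without any pipeline code
  withr::with_seed(101, {
    n <- 50000
    n_pat <- cfg$n_patients
    hf <- (1 - cfg$effect_ratio_ovh + cfg$effect_ratio_hvl) / 2
    aff <- runif(n) < cfg$frac_affected_genes
    x <- rnorm(n)
    delta <- ifelse(aff, cfg$effect_scale_ovl * sign(x) * (0.5 + abs(x)), 0)
    sdf <- cfg$noise_sd[["rna"]] *
      sqrt(cfg$var_prior_df / rchisq(n, cfg$var_prior_df))
    # shared low-grade noise couples the two contrast estimates
    e_o <- rnorm(n, sd = sdf / sqrt(n_pat))
    e_h <- rnorm(n, sd = sdf / sqrt(n_pat))
    e_l <- rnorm(n, sd = sdf / sqrt(n_pat))
    rho_oracle <- cor(delta + e_o - e_l, hf * delta + e_h - e_l,
                      method = "spearman")
  })
  expect_gt(rho_pipeline, 0)
  expect_lt(abs(rho_pipeline - rho_oracle), 0.15)
})

test_that("doubling the effect scale does not decrease the significant count", {
  wins <- vapply(1:3, function(seed) {
    lo <- generate_dataset(quick_sim_config(seed = seed, n_genes = 500,
                                            effect_scale_ovl = 1))
    hi <- generate_dataset(quick_sim_config(seed = seed, n_genes = 500,
                                            effect_scale_ovl = 2))
    n_lo <- length(significant_features(diff_paired(lo$layers$rna, "O_vs_L"), 0.05))
    n_hi <- length(significant_features(diff_paired(hi$layers$rna, "O_vs_L"), 0.05))
    n_hi >= n_lo
  }, TRUE)
  expect_gte(sum(wins), 2)
})

test_that("a planted set of affected genes ranks first by combined enrichment P", {
  ranks_first <- vapply(1:5, function(seed) {
    cfg <- quick_sim_config(
      seed = seed, n_genes = 500, n_proteins = 350,
      planted_sets = list(list(name = "target", size = 50, affected_frac = 1)),
      n_decoy_sets = 30)
    run <- run_pipeline(run_config(sim = cfg, enrich_n_rand = 200, seed = seed))
    en <- run$enrichment
    en$set[which.min(en$combined_p)] == "target"
  }, TRUE)
  expect_gte(sum(ranks_first), 4)
})

test_that("simulated datasets round-trip through the plain-text export", {
  sim <- generate_dataset(quick_sim_config(seed = 5, n_genes = 50,
                                           n_proteins = 30, n_decoy_sets = 3))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  rna <- read_layer_tsv(file.path(dir, "rna.tsv"), "rna")
  expect_equal(rna$values, sim$layers$rna$values)
  expect_equal(rna$samples$grade, sim$layers$rna$samples$grade)
  meth <- read_layer_tsv(file.path(dir, "methylation.tsv"), "methylation",
                         is_beta = TRUE)
  expect_equal(meth$values, sim$layers$methylation$values)
  ann <- read_probe_annotation(file.path(dir, "probes.bed"))
  expect_equal(ann$pos, sim$probe_annotation$pos)
  expect_equal(ann$gene, sim$probe_annotation$gene)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_equal(sets[names(sim$gene_sets)], sim$gene_sets, ignore_attr = TRUE)
})
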