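fake_diff <- function(genes, logFC, q, contrast = "O_vs_L", layer = "rna",
                      ci_half = 0.5) {
  out <- tibble::tibble(feature = genes, logFC = logFC, q = q,
                        p = q, ci_lo = logFC - ci_half,
                        ci_hi = logFC + ci_half)
  class(out) <- c("diff_result", class(out))
  attr(out, "contrast") <- contrast
  attr(out, "layer") <- layer
  out
}

test_that("gene-ID mapping keeps only one-to-one pairs", {
  keep_both <- tibble::tibble(ensembl_id = c("E1", "E2"),
                              gene_name = c("A", "B"))
  expect_identical(nrow(map_gene_ids(keep_both)), 2L)

  dup_name <- tibble::tibble(ensembl_id = c("E1", "E2"),
                             gene_name = c("A", "A"))
  expect_identical(nrow(map_gene_ids(dup_name)), 0L)

  mixed <- tibble::tibble(ensembl_id = c("E1", "E1", "E2"),
                          gene_name = c("A", "B", "C"))
  out <- map_gene_ids(mixed)
  expect_identical(out$ensembl_id, "E2")
  expect_identical(out$gene_name, "C")
})

test_that("triple overlap intersects RNA, protein and DMR-overlapped genes", {
  rna <- fake_diff(c("g1", "g2", "g3"), c(1, -1, 2), c(1e-4, 1e-4, 0.5))
  prot <- fake_diff(c("g1", "g2", "g3"), c(2, 1, 1), c(1e-4, 0.5, 1e-4),
                    layer = "protein")
  disjoint <- triple_overlap(rna, prot, c("g3"), fdr = 0.001)
  expect_identical(nrow(disjoint), 0L)

  hit <- triple_overlap(rna, prot, c("g1"), fdr = 0.001)
  expect_identical(hit$gene, "g1")
  expect_identical(hit$rna_direction, 1)
  expect_true(hit$rna_protein_concordant)

  # order-independence and idempotence of the gene list
  hit2 <- triple_overlap(rna[3:1, ], prot[c(2, 1, 3), ], c("g1"), fdr = 0.001)
  expect_identical(hit$gene, hit2$gene)
  expect_equal(hit$rna_logFC, hit2$rna_logFC)
})

test_that("secondary-contrast support flags require all three layers", {
  rna <- fake_diff(c("g1", "g2"), c(1, 1), c(1e-4, 1e-4))
  prot <- fake_diff(c("g1", "g2"), c(1, 1), c(1e-4, 1e-4), layer = "protein")
  sec_rna <- fake_diff(c("g1", "g2"), c(1, 1), c(0.01, 0.5))
  sec_prot <- fake_diff(c("g1", "g2"), c(1, 1), c(0.01, 0.01),
                        layer = "protein")
  out <- triple_overlap(rna, prot, c("g1", "g2"), fdr = 0.001,
                        secondary = list(rna = sec_rna, protein = sec_prot,
                                         dmr_genes = c("g1", "g2")),
                        secondary_fdr = 0.05)
  expect_identical(out$o_vs_h_supported, c(TRUE, FALSE))
})

test_that("exact binomial concordance matches enumeration and the published bounds", {
  expect_equal(binomial_concordance(52, 56), 5.504028e-12, tolerance = 1e-6)
  expect_lte(binomial_concordance(52, 56), 1e-10)
  expect_equal(binomial_concordance(18, 18), 2^-18)
  expect_lte(binomial_concordance(18, 18), 1e-5)
  expect_equal(binomial_concordance(0, 10), 1)

  # enumeration oracle for all (k, n) with n <= 25
  for (n in c(1, 5, 12, 25)) {
    for (k in c(0, 1, floor(n / 2), n)) {
      oracle <- sum(choose(n, k:n)) / 2^n
      expect_equal(binomial_concordance(k, n), oracle, tolerance = 1e-12)
    }
  }
})

test_that("contrast correlation recovers identity and antisymmetry", {
  withr::with_seed(2, {
    d <- fake_diff(sprintf("g%d", 1:50), rnorm(50), runif(50))
  })
  self <- contrast_correlation(d, d)
  expect_equal(self$spearman_rho, 1)
  expect_equal(self$proportion, 1)
  expect_equal(self$ci_overlap_fraction, 1)

  neg <- d
  neg$logFC <- -d$logFC
  flipped <- contrast_correlation(d, neg)
  expect_equal(flipped$spearman_rho, -1)

  expect_error(contrast_correlation(d[1:2, ], d[1:2, ]), "3 shared",
               class = "triomix_config_error")
})

test_that("estimated cross-contrast structure mirrors the generator", {
  sim <- generate_dataset(quick_sim_config(seed = 6, n_genes = 600))
  ovl <- diff_paired(sim$layers$rna, "O_vs_L")
  hvl <- diff_paired(sim$layers$rna, "H_vs_L")
  rep_ <- contrast_correlation(ovl, hvl)
  expect_gt(rep_$spearman_rho, 0)
  expect_lt(rep_$binomial_p, 0.05)
})

test_that("PCA separates a planted axis but not pure noise", {
  s <- paired_samples(9)
  withr::with_seed(4, {
    signal <- matrix(rnorm(50 * nrow(s)), 50)
    signal[, s$grade == "osteophytic"] <- signal[, s$grade == "osteophytic"] + 4
    dimnames(signal) <- list(sprintf("f%d", 1:50), s$sample_id)
    noise <- matrix(rnorm(50 * nrow(s)), 50,
                    dimnames = list(sprintf("f%d", 1:50), s$sample_id))
  })
  sep <- pca_separation(omics_layer(signal, "rna", s), rownames(signal))
  expect_true(attr(sep, "separated"))
  expect_identical(nrow(sep), nrow(s))

  not_sep <- pca_separation(omics_layer(noise, "rna", s), rownames(noise))
  expect_false(attr(not_sep, "separated"))
})

test_that("PCA scores are invariant to feature order up to sign", {
  ly <- withr::with_seed(10, random_layer(40, n_patients = 6))
  a <- pca_separation(ly, rownames(ly$values))
  b <- pca_separation(ly, rev(rownames(ly$values)))
  expect_equal(abs(a$PC1), abs(b$PC1), tolerance = 1e-8)
  expect_identical(attr(a, "separated"), attr(b, "separated"))
  expect_error(pca_separation(ly, character(0)),
               class = "triomix_config_error")
})

test_that("concordant fraction among triple-significant genes exceeds one half", {
  wins <- vapply(1:5, function(seed) {
    sim <- generate_dataset(quick_sim_config(seed = seed, n_genes = 500,
                                             n_proteins = 350,
                                             rna_protein_corr = 0.6))
    rna <- diff_paired(sim$layers$rna, "O_vs_L")
    prot <- diff_paired(normalize_protein(sim$layers$protein), "O_vs_L")
    m <- beta_to_m(sim$layers$methylation, clip = 1e-6)
    md <- diff_paired(m, "O_vs_L")
    dmr <- overlap_genes(call_dmrs(md, sim$probe_annotation),
                         sim$gene_intervals, md, sim$probe_annotation)
    tri <- triple_overlap(rna, prot, dmr, fdr = 0.01)
    if (nrow(tri) < 5) return(NA)
    k <- sum(tri$rna_protein_concordant)
    binomial_concordance(k, nrow(tri)) < 0.05
  }, TRUE)
  expect_gte(sum(wins, na.rm = TRUE), 4)
})
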