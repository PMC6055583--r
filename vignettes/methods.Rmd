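---
title: "Methods: paired cross-omics differential analysis and integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired cross-omics differential analysis and integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`triomix` analyses matched multi-omics data from a within-individual
three-grade tissue design: every patient contributes one chondrocyte sample
from osteophytic, high-grade and low-grade articular cartilage, assayed on
methylation probes, RNA and protein. This vignette documents the models,
the parameters that matter, the numerical choices, and what the synthetic
testbed does and does not establish.

## The paired differential model

For a feature on one layer and a two-grade contrast, the model is a
per-feature least-squares fit with patient indicator covariates plus the
tissue term. Because the design is fully paired, this is algebraically the
one-sample analysis of within-patient differences $d_i$: the log2 fold
change is $\widehat{\beta} = \bar d$ (positive means higher in the
first-named tissue), the residual variance is $s^2 = \mathrm{Var}(d_i)$
with $df = n - 1$ (n = 9 patients by default), and the unscaled standard
error is $1/\sqrt{n}$. Patient-level intercepts cancel exactly, which is
the point of the paired design.

Variance moderation follows the standard empirical-Bayes hierarchy: each
true variance $\sigma^2_g$ is drawn from a scaled inverse chi-square prior
with parameters $(d_0, s_0^2)$, so $s^2_g \sim s_0^2 F(df, d_0)$. Both
hyperparameters are estimated by method of moments on $\log s^2_g$: the
excess of $\mathrm{Var}(\log s^2)$ over $\psi'(df/2)$ identifies
$\psi'(d_0/2)$, inverted by Newton iteration on the trigamma function
(relative tolerance $10^{-8}$, bisection fallback), and the mean of
$\log s^2$ then gives $s_0^2$ in closed form through digamma terms. When
the observed spread of $\log s^2$ does not exceed chi-square sampling
noise, $d_0 = \infty$: variances are treated as exchangeable, the
posterior variance is $s_0^2$ everywhere and the statistic has a normal
reference. The moderated statistic is
$t = \widehat\beta \big/ (\tilde s/\sqrt n)$ with
$\tilde s^2 = (d_0 s_0^2 + df\, s^2)/(d_0 + df)$ on $d_0 + df$ degrees of
freedom; $d_0 = 0$ recovers the ordinary paired t-test exactly, which is
how the implementation is checked against a textbook oracle. The unit
tests also verify agreement with an independent reference implementation
of the same estimator to $10^{-8}$.

Two-sided P-values are used throughout; confidence intervals on the logFC
use the t quantile at $d_0 + df$ degrees of freedom. Multiplicity is
handled by Benjamini–Hochberg step-up per layer and contrast. Two working
thresholds run through the package: a primary FDR of 0.001 (headline
significance) and a secondary FDR of 0.05 (supporting evidence in the
secondary contrast). RNA enters as log2 expression and is tested with the
plain moderated t — no count weighting; this is an explicit assumption,
appropriate because quantified log-expression rather than raw counts is
the input contract.

## Preprocessing

Protein abundances are divided by the sample total (so the pre-log matrix
has unit column sums), log2-transformed and quantile normalized against
the common rank-mean reference, with average-rank tie handling; the
normalization is applied jointly across all 27 samples, one reference
distribution, rather than within tissue groups. No pseudo-count is added
before the log: complete-case filtering precedes it, so sum-normalized
fractions are strictly positive; an `epsilon` argument exists for user
data containing zeros, because a forced offset would otherwise distort the
quantiles. Methylation betas are mapped to M-values
$M = \log_2\!\big(\beta/(1-\beta)\big)$; boundary betas are an error
unless a clip bound is supplied (the pipeline uses $10^{-6}$). Raw-array
normalization (funnorm-style) and probe-filtering heuristics are out of
scope: the generator emits already-normalized betas.

## DMR calling

The region caller is deliberately transparent rather than a reproduction
of kernel-smoothing machinery: probes significant at the probe-level FDR
(0.001 by default, matching the primary threshold) are sorted and merged
into maximal runs in which consecutive significant probes on one
chromosome are at most `lambda_bp` = 1000 bp apart; runs with fewer than
`min_probes` = 2 probes are discarded. These defaults mirror the
bandwidth-and-support spirit of the standard 450k region callers. Each
region's P-value is a signed Stouffer combination of its member probes,
$z_i = \Phi^{-1}(1 - p_i/2)\,\mathrm{sign}(\mathrm{logFC}_i)$ and
$P = 1 - \Phi\!\big(|\sum_i z_i|/\sqrt m\big)$; a region mixing
methylation directions can self-cancel, which is accepted and documented —
regions are assembled from individually significant probes, so mixtures
are rare. Regions are BH-adjusted. Coordinates are 1-based inclusive
internally; a region overlaps a gene iff the intervals share at least one
base (adjacency does not count), and exported BED files use the 0-based
half-open dialect. Per overlapped gene, DMPs inside overlapping regions
and annotated to that gene are counted, with the proportion showing
increased methylation in the first-named tissue.

## Integration and enrichment

Triple-significant genes are those significant at the primary FDR on RNA
and protein that also overlap a DMR. Directional concordance is RNA-vs-
protein sign agreement only (methylation direction is reported — majority
of the gene's DMPs hypermethylated — but not part of the concordance
test). Concordance is tested with the exact binomial upper tail
$P(X \ge k)$, $X \sim \mathrm{Bin}(n, 1/2)$, by summation. The one-sided
tail was chosen because excess concordance is the alternative of interest;
the package exposes the count and total so a reader preferring the
two-sided convention can double the value.

Cross-contrast structure is summarised by Spearman rank correlation of the
logFC profiles, the same-direction fraction with its binomial tail, and
the fraction of features whose 95% CIs intersect across contrasts
(interval-intersection, non-empty). PCA uses centred, unscaled `prcomp` on
the samples restricted to the significant features; the separation verdict
is an exhaustive 1-D threshold on PC1 (perfect classification of
osteophytic vs both articular grades), with an LDA on the PC1–PC2 plane as
a deterministic fallback.

Gene-set enrichment per layer is the one-sided hypergeometric tail on the
overlap of the layer's significant genes with the set inside the layer's
testable universe (RNA: all genes; protein: quantified proteins;
methylation: genes carrying probes, with "significant" meaning overlapped
by a DMR). The three P-values are combined with Fisher's method
($X^2 = -2\sum \ln p$, $\chi^2_6$ reference). The combination rule is a
pluggable design choice — rank- or Stouffer-based alternatives would fit
the same interface — and deliberately carries little inferential weight,
because final significance comes from a randomization null: each
randomization independently re-draws every layer's significant list
uniformly from that layer's universe (preserving list sizes), all combined
statistics are recomputed, and the integrative FDR of an observed value is
the mean null count at or below it divided by the observed count, clipped
to [0, 1] and monotonized. Label randomization rather than sample
permutation was chosen because it matches the gene-set null being tested
and avoids refitting the differential models thousands of times. Records
are then filtered for multi-layer support: per-layer enrichment P < 0.05
on at least two layers, and at least five contributing genes (the overlap
count N) on at least two layers; "contributing genes" is interpreted as N.
P-values of exactly zero are clipped to $10^{-300}$ before logs.

## The synthetic testbed

The generator is the package's ground-truth instrument. Per gene it draws
an affected flag (20% by default), a latent effect, a patient random
intercept (SD 0.5) and Gaussian noise; grade means are low = 0,
osteophytic = $\delta$, high = $h\delta$. Because group-mean differences
are additive, the two attenuation parameters cannot hold simultaneously as
exact ratios ($0.9 + 0.3 \ne 1$), so the high-grade position is their
symmetric reconciliation $h = (1 - r_{OvH} + r_{HvL})/2 = 0.2$: high-vs-low
effects are strongly attenuated, osteophytic-vs-high effects nearly as
large as osteophytic-vs-low, and all three directionally aligned — the
qualitative structure the design encodes.

Effect sizes are $\delta = s\,\mathrm{sign}(x)(0.5 + |x|)$ with $x$
standard normal and scale $s = 2$: a magnitude floor of $s/2$ keeps
planted effects detectable at n = 9 (a pure Gaussian effect distribution
would put much of its mass at undetectably small effects and make "recall
of affected genes" ill-posed). RNA and protein effects share a latent
factor with correlation 0.6; since the transform is strictly increasing,
rank correlations survive it. The methylation effect direction is drawn
independently of expression — in matched tissue data both hyper- and
hypomethylated genes occur among both up- and down-regulated genes — and
is applied coherently to every probe of the gene. Residual SDs default to
0.5 (M-value), 0.6 (log2 RNA) and 0.8 (log2 protein), plausible
within-pair scales for these platforms, and per-feature variances are
drawn from a scaled inverse chi-square around them (`var_prior_df` = 20),
giving the variance heterogeneity that makes moderation non-trivial. The
within-patient intercept SD is a free parameter, not calibrated to any
study — it cancels from all paired statistics and only matters for
unpaired misuse. Genes are tiled on one synthetic chromosome as 2 kb
probe-dense bodies at 10 kb pitch, ~10 probes per gene, so regions never
merge across genes at the default `lambda_bp`; protein covers a random
1200-of-2000 gene subset ("quantified in all individuals", so no
missingness by default); five planted sets of 40 genes (80% affected
members) sit among 95 random decoys. Default sizes are a deliberate
scale-down of a 14k-gene/4.6k-protein/425k-probe experiment that keeps
every statistical property testable in seconds.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: batch and array-chemistry effects,
count-distributed RNA noise, protein missingness mechanisms,
between-feature correlation beyond shared gene effects (probes of a gene
share only the planted shift, not local co-methylation), CpG-island
structure, and cell-composition confounding. Decoy gene sets can overlap
truly affected genes by chance, so on signal-bearing simulations some
decoys are genuinely (not spuriously) enriched; FDR calibration is instead
assessed on label-randomized null lists.

## Problem sizes and determinism

Every stochastic step runs under an explicit seed (`withr::with_seed`), and
a fixed configuration reproduces byte-identical datasets and summaries.
The test suite checks calibration with 5,000 null features across 20 seeds
(raw P < 0.05 rate within [0.04, 0.06] pooled), enrichment FDR control
with 100 random sets, 1,000 randomizations and 20 seeds (≤ 7.5% of sets at
q ≤ 0.05), recovery on the default 2,000-gene conditions across 3 seeds
(affected-gene recall ≥ 0.8 at 5% FDR with empirical FDR ≤ 7.5%; planted
set recall ≥ 0.8 at q ≤ 0.05), and the attenuation structure across 20
seeds (more primary- than articular-contrast hits, positive cross-contrast
correlation, PCA separation, each in ≥ 90% of seeds). These sizes were
chosen as the smallest at which the binomial/Monte-Carlo error of each
check is comfortably below its margin.

## Known limitations

The DMR caller is a transparent gap-merge procedure, not a kernel-smoothed
one; its absolute region counts are not comparable to other callers'.
Fisher combination treats the three layers as independent, which the
randomization null corrects only at the level of the final FDR. The
concordance test conditions on the triple-significant list rather than
modelling selection. The separation verdict is binary by construction and
silent about margin width.
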