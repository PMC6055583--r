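#' Per-feature paired fit for one tissue contrast
#'
#' Fits the within-individual paired design for a two-grade contrast. With
#' patient indicators as covariates this is equivalent, feature by feature,
#' to the one-sample analysis of within-patient differences: `logFC` is the
#' mean paired difference (positive = higher in the first-named grade), `s2`
#' the sample variance of the differences, and `df_resid = n_patients - 1`.
#'
#' @param layer An `omics_layer` (values on a log-like scale).
#' @param contrast `"O_vs_L"`, `"O_vs_H"` or `"H_vs_L"`.
#' @return A tibble with columns `feature`, `logFC`, `s2`, `df_resid`, and
#'   attribute `n_pairs`.
#' @export
paired_fit <- function(layer, contrast) {
  stopifnot(inherits(layer, "omics_layer"))
  gr <- contrast_grades(contrast)
  assert_paired(layer, grades = gr)
  s <- layer$samples
  patients <- unique(s$patient)
  col_of <- function(grade) {
    idx <- match(paste0(patients, "_", grade),
                 paste0(s$patient, "_", s$grade))
    layer$values[, idx, drop = FALSE]
  }
  d <- col_of(gr[1]) - col_of(gr[2])
  n <- length(patients)
  mu <- rowMeans(d)
  out <- tibble(
    feature = rownames(layer$values),
    logFC = unname(mu),
    s2 = unname(rowSums((d - mu)^2) / (n - 1)),
    df_resid = n - 1
  )
  attr(out, "n_pairs") <- n
  out
}

# Newton inversion of the trigamma function (solve trigamma(y) = x),
# with a bisection fallback; tolerance 1e-8 on the relative step
trigamma_inverse <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) return(y)
  }
  # fallback: bisect on the strictly decreasing trigamma
  lo <- 1e-8; hi <- 1e8
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > x) lo <- mid else hi <- mid
    if ((hi - lo) / lo < 1e-8) break
  }
  sqrt(lo * hi)
}

# method-of-moments fit of the scaled-F variance prior from log s2:
# E[log s2] and Var[log s2] identify (d0, s0^2) via digamma/trigamma
fit_variance_prior <- function(s2, df) {
  if (length(s2) < 2L) config_error("need >= 2 features to estimate the variance prior")
  if (any(s2 <= 0)) {
    smin <- min(s2[s2 > 0], 1e-12)
    s2 <- pmax(s2, smin * 1e-3)  # guard degenerate zero-variance features
  }
  e <- log(s2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L)
  rhs <- evar - trigamma(df / 2)
  if (rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_2 <- exp(emean - digamma(df / 2) + log(df / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
  } else {
    # observed spread no larger than chi-square sampling noise: variances
    # are exchangeable and the prior is effectively infinitely informative
    d0 <- Inf
    s0_2 <- exp(emean - digamma(df / 2) + log(df / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks per-feature variances toward a common prior `s0^2` with prior
#' degrees of freedom `d0`, both estimated by method of moments from the
#' distribution of `log(s2)` (closed form via trigamma inversion). The
#' moderated statistic is `t = logFC / (s_tilde * se_unscaled)` with
#' `s_tilde^2 = (d0*s0^2 + df*s2) / (d0 + df)`, referred to a t distribution
#' on `df_total = d0 + df` degrees of freedom (normal limit when
#' `d0 = Inf`). `d0 = 0` reproduces the ordinary paired t-test.
#'
#' @param s2 Per-feature residual variances.
#' @param df_resid Residual degrees of freedom (scalar).
#' @param logFC Per-feature effect estimates.
#' @param se_unscaled Unscaled standard error of `logFC` (for the paired
#'   design, `1/sqrt(n_pairs)`).
#' @param d0,s0_2 Optional forced prior values overriding estimation
#'   (`d0 = 0` gives the ordinary t; `d0 = Inf` the pooled-variance normal
#'   limit).
#' @return A list with `t`, `p`, `df_total`, `s2_post`, `d0`, `s0_2`.
#' @export
ebayes_moderate <- function(s2, df_resid, logFC, se_unscaled,
                            d0 = NULL, s0_2 = NULL) {
  stopifnot(length(s2) == length(logFC), df_resid >= 1)
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, df_resid)
    d0 <- prior$d0
    if (is.null(s0_2)) s0_2 <- prior$s0_2
  } else if (is.null(s0_2)) {
    s0_2 <- if (d0 > 0) fit_variance_prior(s2, df_resid)$s0_2 else 0
  }
  if (is.infinite(d0)) {
    s2_post <- rep_len(s0_2, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_2 + df_resid * s2) / (d0 + df_resid)
    df_total <- d0 + df_resid
  }
  t_mod <- logFC / (sqrt(s2_post) * se_unscaled)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  list(t = t_mod, p = p, df_total = df_total, s2_post = s2_post,
       d0 = d0, s0_2 = s0_2)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment with monotonicity enforcement; thresholding the
#' result at `alpha` reproduces the classical BH rejection set at level
#' `alpha`.
#'
#' @param p Vector of P-values in `[0, 1]`.
#' @return Adjusted values `q` of the same length.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    config_error("p-values must be numeric in [0, 1] with no NA")
  }
  p.adjust(p, method = "BH")
}

#' Paired differential analysis of one layer and one contrast
#'
#' Runs [paired_fit()], [ebayes_moderate()] and [bh_adjust()] and returns the
#' per-feature table with two-sided P-values, BH-adjusted `q`, and a
#' t-based confidence interval on `logFC` at `df_total` degrees of freedom.
#'
#' @param layer An `omics_layer`.
#' @param contrast `"O_vs_L"`, `"O_vs_H"` or `"H_vs_L"`.
#' @param d0,s0_2 Optional forced moderation prior (see [ebayes_moderate()]).
#' @param conf_level Confidence level for the logFC interval (default 0.95).
#' @return A `diff_result` tibble with columns `feature`, `logFC`, `s2`,
#'   `df_resid`, `t`, `df_total`, `p`, `q`, `ci_lo`, `ci_hi`; attributes
#'   `layer`, `contrast`, `n_pairs`, `d0`, `s0_2`.
#' @export
diff_paired <- function(layer, contrast, d0 = NULL, s0_2 = NULL,
                        conf_level = 0.95) {
  fit <- paired_fit(layer, contrast)
  n <- attr(fit, "n_pairs")
  mod <- ebayes_moderate(fit$s2, fit$df_resid[1], fit$logFC,
                         se_unscaled = 1 / sqrt(n), d0 = d0, s0_2 = s0_2)
  half <- qt(1 - (1 - conf_level) / 2, df = mod$df_total) *
    sqrt(mod$s2_post) / sqrt(n)
  out <- tibble(
    feature = fit$feature, logFC = fit$logFC, s2 = fit$s2,
    df_resid = fit$df_resid, t = mod$t, df_total = mod$df_total,
    p = mod$p, q = bh_adjust(mod$p),
    ci_lo = fit$logFC - half, ci_hi = fit$logFC + half
  )
  class(out) <- c("diff_result", class(out))
  attr(out, "layer") <- layer$layer
  attr(out, "contrast") <- contrast
  attr(out, "n_pairs") <- n
  attr(out, "d0") <- mod$d0
  attr(out, "s0_2") <- mod$s0_2
  out
}

#' @method tidy diff_result
#' @export
tidy.diff_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "diff_result")
  out
}

#' One-row summary of a differential analysis
#'
#' @param x A `diff_result`.
#' @param primary_fdr,secondary_fdr FDR thresholds for the significance
#'   counts (defaults 0.001 and 0.05).
#' @param ... Unused.
#' @return A one-row tibble with the layer, contrast, moderation prior and
#'   significance counts.
#' @method glance diff_result
#' @export
glance.diff_result <- function(x, primary_fdr = 0.001, secondary_fdr = 0.05,
                               ...) {
  tibble(
    layer = attr(x, "layer"), contrast = attr(x, "contrast"),
    n_features = nrow(x), n_pairs = attr(x, "n_pairs"),
    d0 = attr(x, "d0"), s0_2 = attr(x, "s0_2"),
    n_sig_primary = sum(x$q <= primary_fdr),
    n_sig_secondary = sum(x$q <= secondary_fdr)
  )
}

#' Features significant at an FDR threshold
#'
#' @param result A `diff_result` (or any tibble with `feature` and `q`).
#' @param fdr FDR threshold; defaults 0.001 (primary) elsewhere in the
#'   pipeline, 0.05 here.
#' @return Character vector of feature IDs with `q <= fdr`.
#' @export
significant_features <- function(result, fdr = 0.05) {
  stopifnot(all(c("feature", "q") %in% names(result)))
  result$feature[result$q <= fdr]
}
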