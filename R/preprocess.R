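#' Normalize a raw protein abundance layer
#'
#' Abundances are normalized by the sum of all protein abundances in each
#' sample, log2-transformed and quantile normalized across samples. The
#' pre-log sum-normalized matrix has unit column sums; quantile normalization
#' uses the average-rank tie convention (ties receive the mean of the
#' reference values at their rank positions).
#'
#' With complete-case filtering ahead of this step the sum-normalized
#' fractions are strictly positive, so no pseudo-count is needed; `epsilon`
#' is available for user data containing exact zeros.
#'
#' @param layer An `omics_layer` of raw (non-negative) protein abundances.
#' @param epsilon Offset added before log2 (default 0).
#' @return An `omics_layer` of normalized log2 protein fractions.
#' @export
normalize_protein <- function(layer, epsilon = 0) {
  stopifnot(inherits(layer, "omics_layer"), layer$layer == "protein")
  v <- layer$values
  if (any(v < 0, na.rm = TRUE)) config_error("protein abundances must be >= 0")
  cs <- colSums(v, na.rm = TRUE)
  zero <- colnames(v)[cs == 0]
  if (length(zero)) {
    config_error(sprintf("sample(s) with zero total abundance: %s",
                         paste(zero, collapse = ", ")))
  }
  frac <- sweep(v, 2L, cs, "/")
  logged <- log2(frac + epsilon)
  if (any(!is.finite(logged[!is.na(logged)]))) {
    config_error("log2 produced non-finite values; set a positive 'epsilon' or filter zeros first")
  }
  qn <- quantile_normalize(logged)
  dimnames(qn) <- dimnames(v)
  omics_layer(qn, "protein", layer$samples)
}

#' Quantile normalization across samples
#'
#' Maps every sample (column) onto the common reference distribution of
#' per-rank means; ties receive the mean of the reference values at their
#' rank positions (average-rank convention). Idempotent: a second pass
#' leaves an already-normalized matrix unchanged.
#'
#' @param m Numeric matrix, features by samples.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(m) {
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Keep only features quantified in every sample
#'
#' Mirrors a complete-case restriction: features with any missing value
#' (`NA`) in any sample are dropped; retained values and feature order are
#' unchanged.
#'
#' @param layer An `omics_layer`.
#' @return The filtered `omics_layer` (possibly with zero features, with a
#'   warning).
#' @export
filter_complete <- function(layer) {
  stopifnot(inherits(layer, "omics_layer"))
  keep <- rowSums(is.na(layer$values)) == 0L
  if (!any(keep)) warn("filter_complete: no feature is complete in all samples")
  out <- layer
  out$values <- layer$values[keep, , drop = FALSE]
  out
}

#' Convert methylation beta values to M-values
#'
#' M = log2(beta / (1 - beta)), elementwise. Betas must lie strictly inside
#' (0, 1); callers with boundary values clip first with `clip`.
#'
#' @param layer A beta-flagged methylation `omics_layer`.
#' @param clip Optional bound in (0, 0.5): betas are clipped into
#'   `[clip, 1 - clip]` before the transform. `NULL` (default) means no
#'   clipping and boundary values are an error.
#' @return A methylation `omics_layer` of M-values (`is_beta = FALSE`).
#' @export
beta_to_m <- function(layer, clip = NULL) {
  stopifnot(inherits(layer, "omics_layer"), layer$layer == "methylation")
  b <- layer$values
  if (!is.null(clip)) {
    check_number(clip, "clip", lower = 1e-12, upper = 0.5 - 1e-12)
    b <- pmin(pmax(b, clip), 1 - clip)
  }
  if (any(b <= 0 | b >= 1, na.rm = TRUE)) {
    config_error("beta values at or outside (0, 1); pre-clip via 'clip'")
  }
  out <- layer
  out$values <- log2(b / (1 - b))
  out$is_beta <- FALSE
  out
}
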