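#' Construct an omics layer
#'
#' An `omics_layer` bundles one feature-by-sample numeric matrix with its
#' layer label and sample metadata. It is the unit every statistical stage
#' consumes. Samples follow a fully paired design: each patient contributes
#' one sample per tissue grade (`low`, `high`, `osteophytic`).
#'
#' @param values Numeric matrix, features in rows (rownames = feature IDs),
#'   samples in columns (colnames = sample IDs).
#' @param layer One of `"methylation"`, `"rna"`, `"protein"`.
#' @param samples Data frame with columns `sample_id`, `patient`, `grade`,
#'   one row per column of `values`, in column order.
#' @param is_beta Logical; `TRUE` when methylation values are beta proportions
#'   in (0, 1) rather than M-values.
#'
#' @return An object of class `omics_layer`.
#' @export
omics_layer <- function(values, layer, samples, is_beta = FALSE) {
  layer <- match.arg(layer, LAYERS)
  if (!is.matrix(values) || !is.numeric(values)) {
    config_error("'values' must be a numeric matrix")
  }
  samples <- as_tibble(samples)
  stopifnot(all(c("sample_id", "patient", "grade") %in% names(samples)))
  if (nrow(samples) != ncol(values)) {
    config_error("'samples' must have one row per column of 'values'")
  }
  if (!all(samples$grade %in% GRADES)) {
    config_error("sample grades must be one of low/high/osteophytic")
  }
  if (anyDuplicated(rownames(values))) {
    config_error("duplicate feature IDs in 'values'")
  }
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (isTRUE(is_beta)) {
    finite <- values[is.finite(values)]
    if (any(finite <= 0 | finite >= 1)) {
      config_error("beta values must lie strictly in (0, 1)")
    }
  }
  structure(
    list(values = values, layer = layer, samples = samples,
         is_beta = isTRUE(is_beta)),
    class = "omics_layer"
  )
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer: %s> %d features x %d samples (%d patients)%s\n",
              x$layer, nrow(x$values), ncol(x$values),
              length(unique(x$samples$patient)),
              if (x$is_beta) " [beta]" else ""))
  invisible(x)
}

#' @export
dim.omics_layer <- function(x) dim(x$values)

#' Long-format view of an omics layer
#'
#' @param x An `omics_layer`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `sample_id`, `patient`, `grade`,
#'   `value`.
#' @method tidy omics_layer
#' @export
tidy.omics_layer <- function(x, ...) {
  tibble(
    feature = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$values)),
    patient = rep(x$samples$patient, each = nrow(x$values)),
    grade = rep(x$samples$grade, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

# check each patient has every requested grade exactly once
assert_paired <- function(layer, grades = GRADES) {
  s <- layer$samples[layer$samples$grade %in% grades, ]
  tab <- table(s$patient, factor(s$grade, levels = grades))
  bad <- rownames(tab)[apply(tab != 1L, 1L, any)]
  if (length(bad)) {
    abort(sprintf("unpaired design: patient(s) %s lack one sample per grade (%s)",
                  paste(bad, collapse = ", "), paste(grades, collapse = ", ")),
          class = "triomix_pairing_error")
  }
  invisible(layer)
}

#' Write an omics layer to TSV
#'
#' Writes the feature-by-sample matrix with a `feature` ID column and sample
#' IDs `P<i>_<grade>` as the remaining column names.
#'
#' @param layer An `omics_layer`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layer_tsv <- function(layer, path) {
  df <- as.data.frame(layer$values)
  df <- cbind(feature = rownames(layer$values), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' Read an omics layer from TSV
#'
#' Expects the dialect written by [write_layer_tsv()]: a `feature` column and
#' sample columns named `P<i>_<grade>`.
#'
#' @param path TSV file path.
#' @param layer Layer label (`"methylation"`, `"rna"`, `"protein"`).
#' @param is_beta Whether methylation values are beta proportions.
#' @return An `omics_layer`.
#' @export
read_layer_tsv <- function(path, layer, is_beta = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  omics_layer(m, layer, samples_from_ids(colnames(m)), is_beta = is_beta)
}

# parse "P3_high" style sample IDs into metadata
samples_from_ids <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  grade <- vapply(parts, function(p) paste(p[-1], collapse = "_"), "")
  if (!all(grade %in% GRADES)) {
    config_error("sample IDs must look like 'P<i>_<grade>' with grade in low/high/osteophytic")
  }
  tibble(sample_id = ids,
         patient = vapply(parts, `[[`, "", 1L),
         grade = grade)
}
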