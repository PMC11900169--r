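#' Filter genes by counts-per-million
#'
#' Keeps gene g when its mean CPM across samples is at least `cpm_threshold`
#' (the default rule), or — when `min_samples_over_cpm` is given — when at
#' least that many individual samples exceed the threshold. The number of
#' genes removed is recorded in `metadata(se)$preprocess$cpm_removed`.
#'
#' @param se SummarizedExperiment with assay `"counts"`.
#' @param cpm_threshold CPM threshold (default 1).
#' @param min_samples_over_cpm optional integer switching to the per-sample
#'   rule.
#' @return the filtered SummarizedExperiment.
#' @export
cpmFilter <- function(se, cpm_threshold = 1, min_samples_over_cpm = NULL) {
  counts <- SummarizedExperiment::assay(se, "counts")
  lib <- colSums(counts)
  if (all(lib == 0)) stop("all library sizes are zero", call. = FALSE)
  cpm <- t(t(counts) / lib) * 1e6
  keep <- if (is.null(min_samples_over_cpm)) {
    rowMeans(cpm) >= cpm_threshold
  } else {
    rowSums(cpm >= cpm_threshold) >= min_samples_over_cpm
  }
  if (!any(keep))
    stop("CPM filter removed every gene; lower cpm_threshold", call. = FALSE)
  out <- se[keep, ]
  meta <- S4Vectors::metadata(out)$preprocess
  if (is.null(meta)) meta <- list()
  meta$cpm_removed <- sum(!keep)
  meta$cpm_threshold <- cpm_threshold
  S4Vectors::metadata(out)$preprocess <- meta
  out
}

#' TMM scaling factors (Robinson-Oshlack)
#'
#' Thin wrapper over [edgeR::calcNormFactors()]: log2 M/A values on genes
#' positive in both sample and reference, symmetric trimming (30\% on M, 5\%
#' on A by default), precision-weighted mean of the trimmed M values, and
#' re-centering so the factors' geometric mean is 1. When `ref_sample` is
#' absent the sample whose upper-quartile CPM is closest to the mean upper
#' quartile is used, as in edgeR.
#'
#' @param se SummarizedExperiment with assay `"counts"` (already filtered).
#' @param ref_sample optional reference sample id.
#' @param trim_m,trim_a trim fractions for M and A values.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmmFactors <- function(se, ref_sample = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- SummarizedExperiment::assay(se, "counts")
  ref_col <- NULL
  if (!is.null(ref_sample)) {
    ref_col <- match(ref_sample, colnames(counts))
    if (is.na(ref_col))
      stop("ref_sample '", ref_sample, "' not found", call. = FALSE)
  }
  lib <- colSums(counts)
  if (!is.null(ref_col)) {
    shared <- counts[, ref_col] > 0
    dead <- colSums(counts[shared, , drop = FALSE] > 0) == 0
    if (any(dead))
      stop("sample(s) share no positive genes with the reference: ",
           paste(colnames(counts)[dead], collapse = ", "), call. = FALSE)
  }
  f <- edgeR::calcNormFactors(counts, lib.size = lib, method = "TMM",
                              refColumn = ref_col,
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Normalize counts to (length-adjusted) CPM using TMM factors
#'
#' value = count / (library_size * factor) * 1e6, optionally divided by
#' gene length in kb when `use_lengths` is set (RPK-style length
#' adjustment; requires `rowData(se)$gene_length`).
#'
#' @param se SummarizedExperiment with assay `"counts"`.
#' @param factors per-sample factors from [tmmFactors()].
#' @param use_lengths divide by gene length (kb)?
#' @return SummarizedExperiment with assay `"normexpr"`, per-sample factors
#'   in `colData()$norm_factor` and a provenance record in `metadata()`.
#' @export
normalizeCounts <- function(se, factors, use_lengths = FALSE) {
  counts <- SummarizedExperiment::assay(se, "counts")
  if (length(factors) != ncol(counts))
    stop("need one factor per sample", call. = FALSE)
  lib <- colSums(counts)
  vals <- t(t(counts) / (lib * factors)) * 1e6
  if (use_lengths) {
    len <- SummarizedExperiment::rowData(se)$gene_length
    if (is.null(len))
      stop("use_lengths = TRUE but rowData(se)$gene_length is missing",
           call. = FALSE)
    vals <- vals / (len / 1000)
  }
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(normexpr = vals),
    colData = SummarizedExperiment::colData(se),
    rowData = SummarizedExperiment::rowData(se))
  SummarizedExperiment::colData(out)$norm_factor <- unname(factors)
  S4Vectors::metadata(out) <- S4Vectors::metadata(se)
  S4Vectors::metadata(out)$preprocess$normalization <-
    list(method = "TMM-CPM", use_lengths = use_lengths)
  out
}

#' Split a matrix by condition label
#'
#' Returns per-condition SummarizedExperiments over the same gene universe;
#' the sample sets partition the input exactly.
#'
#' @param se SummarizedExperiment whose `colData()$condition` labels every
#'   sample.
#' @param conditions optional subset/order of condition labels to return.
#' @return named list of SummarizedExperiments.
#' @export
stratifyByCondition <- function(se, conditions = NULL) {
  labels <- SummarizedExperiment::colData(se)$condition
  if (is.null(labels) || anyNA(labels))
    stop("every sample must carry a condition label", call. = FALSE)
  levels_here <- unique(labels)
  if (is.null(conditions)) conditions <- levels_here
  unknown <- setdiff(conditions, levels_here)
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stats::setNames(lapply(conditions, function(cc) se[, labels == cc]),
                  conditions)
}

#' Batch-correction hook (pass-through)
#'
#' Placeholder stage in the preprocessing chain where a batch-effect
#' correction could be plugged in; the default is the identity, and the
#' synthetic generator plants no batch structure.
#'
#' @param se SummarizedExperiment.
#' @param correct optional function `se -> se`.
#' @return the (possibly corrected) SummarizedExperiment.
#' @export
batchCorrectHook <- function(se, correct = NULL) {
  if (is.null(correct)) se else correct(se)
}
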