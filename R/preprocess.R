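# Normalization, transformation, purity filtering and per-cohort
# standardization of the expression matrix. The quadrant subtype rule uses
# a 0 threshold, which presupposes a centered scale: batch correction is
# therefore per-cohort gene-wise z-scoring, which both removes additive
# cohort offsets and centers every gene at the cohort-typical level.

#' Preprocessing thresholds
#'
#' @param purityThreshold samples with tumor purity strictly below this are
#'   excluded (default 0.30).
#' @param log2fcThreshold inclusive absolute log2 fold-change cut for the
#'   differential screen (default 1).
#' @param batchMethod `"per_cohort_zscore"` or `"none"`.
#' @return A list of class `preprocessConfig`.
#' @export
preprocessConfig <- function(purityThreshold = 0.30, log2fcThreshold = 1,
                             batchMethod = c("per_cohort_zscore", "none")) {
  if (purityThreshold < 0 || purityThreshold > 1)
    .stopf("purityThreshold must lie in [0, 1]")
  if (log2fcThreshold < 0) .stopf("log2fcThreshold must be >= 0")
  structure(list(purityThreshold = purityThreshold,
                 log2fcThreshold = log2fcThreshold,
                 batchMethod = match.arg(batchMethod)),
            class = "preprocessConfig")
}

#' Transcripts-per-million normalization
#'
#' Per sample, `TPM_i = (count_i / length_i) / sum_j(count_j / length_j) *
#' 1e6`, so every column sums to one million.
#'
#' @param counts an [ExpressionMatrix-class] on the `counts` scale.
#' @param geneLengths named positive gene lengths (any consistent unit);
#'   every gene in `counts` must have one.
#' @return An [ExpressionMatrix-class] on the `tpm` scale.
#' @export
tpmNormalize <- function(counts, geneLengths) {
  if (scaleTag(counts) != "counts")
    .stopf("tpmNormalize expects a counts-scale matrix, got '%s'",
           scaleTag(counts))
  v <- exprValues(counts)
  missing <- setdiff(rownames(v), names(geneLengths))
  if (length(missing))
    .stopf("missing gene length(s): %s", paste(head(missing, 5), collapse = ", "))
  len <- geneLengths[rownames(v)]
  if (any(len <= 0)) .stopf("gene lengths must be positive")
  rates <- v / len
  tot <- colSums(rates)
  if (any(tot == 0))
    .stopf("sample(s) with zero total rate: %s",
           paste(head(colnames(v)[tot == 0], 5), collapse = ", "))
  ExpressionMatrix(sweep(rates, 2, tot, "/") * 1e6, "tpm")
}

#' Log-transform a TPM matrix
#'
#' Elementwise `log10(x + 1)`: monotone, and 0 maps to 0.
#'
#' @param tpm an [ExpressionMatrix-class] on the `tpm` scale.
#' @return An [ExpressionMatrix-class] on the `log10tpm` scale.
#' @export
logTransform <- function(tpm) {
  if (scaleTag(tpm) != "tpm")
    .stopf("logTransform expects a tpm-scale matrix, got '%s'", scaleTag(tpm))
  ExpressionMatrix(log10(exprValues(tpm) + 1), "log10tpm")
}

#' Exclude low-purity samples
#'
#' Removes samples whose tumor purity is strictly below the threshold from
#' both the matrix and the clinical table (a sample at exactly the
#' threshold is retained). Missing purity is an error unless
#' `allowMissing = TRUE`, in which case the sample is retained with a
#' warning. Idempotent.
#'
#' @param em an [ExpressionMatrix-class].
#' @param clinical clinical data.frame covering every sample of `em`.
#' @param threshold purity cut (default 0.30).
#' @param allowMissing retain samples with missing purity instead of
#'   erroring.
#' @return List with elements `expression`, `clinical` and `excluded`
#'   (character vector of removed sample identifiers).
#' @export
filterByPurity <- function(em, clinical, threshold = 0.30,
                           allowMissing = FALSE) {
  ids <- sampleIds(em)
  .checkAligned(ids, clinical$sample_id)
  purity <- clinical$purity[match(ids, clinical$sample_id)]
  if (anyNA(purity)) {
    if (!allowMissing)
      .stopf("missing purity for sample(s): %s",
             paste(head(ids[is.na(purity)], 5), collapse = ", "))
    .warnf("%d sample(s) with missing purity retained", sum(is.na(purity)))
  }
  drop <- !is.na(purity) & purity < threshold
  keep <- ids[!drop]
  list(expression = em[, keep],
       clinical = clinical[clinical$sample_id %in% keep, , drop = FALSE],
       excluded = ids[drop])
}

#' Per-cohort gene-wise standardization
#'
#' Within each cohort, every gene is centered to mean 0 and scaled to unit
#' standard deviation; a gene constant within a cohort is set to 0 with a
#' warning. With a single cohort this is an ordinary gene-wise z-score.
#' Removes additive cohort offsets exactly, so the pooled per-gene mean is
#' ~0 and the quadrant rule's 0 threshold means "at the cohort-typical
#' level".
#'
#' @param em an [ExpressionMatrix-class].
#' @param cohorts cohort label per sample of `em` (named, or in `em` column
#'   order); every cohort needs at least 2 samples.
#' @return An [ExpressionMatrix-class] on the `standardized` scale.
#' @export
batchCorrect <- function(em, cohorts) {
  v <- exprValues(em)
  if (!is.null(names(cohorts))) {
    .checkAligned(colnames(v), names(cohorts), "cohort labels")
    cohorts <- cohorts[colnames(v)]
  } else if (length(cohorts) != ncol(v))
    .stopf("cohort labels must cover every sample")
  small <- names(which(table(cohorts) < 2L))
  if (length(small))
    .stopf("cohort(s) with fewer than 2 samples: %s",
           paste(small, collapse = ", "))
  out <- v
  constant <- FALSE
  for (co in unique(cohorts)) {
    idx <- which(cohorts == co)
    block <- v[, idx, drop = FALSE]
    mu <- rowMeans(block)
    sdv <- apply(block, 1, sd)
    zero <- sdv == 0
    if (any(zero)) { constant <- TRUE; sdv[zero] <- 1 }
    out[, idx] <- (block - mu) / sdv
    out[zero, idx] <- 0
  }
  if (constant)
    .warnf("gene(s) constant within a cohort were set to 0")
  ExpressionMatrix(out, "standardized")
}

#' Differential screen by absolute log2 fold change
#'
#' Returns the genes whose group-mean difference on the log2 scale meets the
#' threshold (inclusive). Values on the `log10tpm` scale are converted to
#' log2 by multiplying with `log2(10)`; `standardized` values are compared
#' as-is.
#'
#' @param em an [ExpressionMatrix-class] on a log or standardized scale.
#' @param groupA,groupB disjoint non-empty sample identifier vectors.
#' @param threshold inclusive absolute difference cut on the log2 scale.
#' @return Character vector of passing gene identifiers.
#' @export
log2fcScreen <- function(em, groupA, groupB, threshold = 1) {
  if (!length(groupA) || !length(groupB)) .stopf("groups must be non-empty")
  if (length(intersect(groupA, groupB))) .stopf("groups must be disjoint")
  v <- exprValues(em)
  .checkAligned(c(groupA, groupB), colnames(v), "matrix")
  diff <- rowMeans(v[, groupA, drop = FALSE]) -
    rowMeans(v[, groupB, drop = FALSE])
  if (scaleTag(em) == "log10tpm") diff <- diff * log2(10)
  rownames(v)[abs(diff) >= threshold]
}
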