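#' @import methods
#' @importFrom stats median sd cor cutree as.dist rexp rnorm runif rbinom rbeta
#'   pt pchisq pnorm setNames complete.cases quantile uniroot
#' @importFrom utils read.delim write.table head combn
NULL

.SCALE_TAGS <- c("counts", "tpm", "log10tpm", "standardized")
.SUBTYPES <- c("quiescent", "glycolytic", "cholesterogenic", "mixed")

#' ExpressionMatrix: a validated gene-by-sample abundance matrix
#'
#' Thin S4 container around a numeric matrix of gene-level abundances with a
#' scale tag recording where the matrix sits in the normalization chain
#' (`counts` -> `tpm` -> `log10tpm` -> `standardized`). Row names are gene
#' identifiers, column names sample identifiers; both must be unique and
#' non-empty, and all values finite. Values must be non-negative on every
#' scale except `standardized`.
#'
#' @slot values numeric matrix, genes in rows, samples in columns.
#' @slot scaleTag one of `"counts"`, `"tpm"`, `"log10tpm"`, `"standardized"`.
#' @aliases ExpressionMatrix
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  representation(values = "matrix", scaleTag = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have gene row names and sample column names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, sprintf("duplicate gene identifiers: %s",
        paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, sprintf("duplicate sample identifiers: %s",
        paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
  }
  if (length(object@scaleTag) != 1L || !object@scaleTag %in% .SCALE_TAGS)
    msg <- c(msg, sprintf("scaleTag must be one of %s",
      paste(.SCALE_TAGS, collapse = ", ")))
  if (is.numeric(v)) {
    if (any(!is.finite(v)))
      msg <- c(msg, "all expression values must be finite")
    else if (length(object@scaleTag) == 1L &&
             object@scaleTag %in% c("counts", "tpm", "log10tpm") && any(v < 0))
      msg <- c(msg, sprintf("negative values are not allowed on the %s scale",
                            object@scaleTag))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @param scaleTag scale of the values; see [ExpressionMatrix-class].
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("G1", "G2"), c("S1", "S2", "S3")))
#' ExpressionMatrix(m, "counts")
#' @export
ExpressionMatrix <- function(values, scaleTag = "counts") {
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, scaleTag = scaleTag)
}

#' SyntheticCohort: all components of a simulated tumor cohort
#'
#' Holds the aligned outputs of [simulateCohort()]: expression, clinical
#' records, copy-number segments, simple mutations, gene coding intervals,
#' the two metabolic gene sets, and the planted per-sample subtype labels.
#' Sample identifiers are identical and aligned across expression columns,
#' clinical rows and truth labels.
#'
#' @slot expression [ExpressionMatrix-class].
#' @slot clinical data.frame with columns `sample_id`, `os_months`, `event`,
#'   `cohort`, `purity`, `metastatic`.
#' @slot segments data.frame of SEG records (`sample_id`, `chrom`, `start`,
#'   `end`, `n_probes`, `seg_mean`, `copy_status`).
#' @slot mutations data.frame (`gene`, `sample`, `class`).
#' @slot geneIntervals data.frame of gene coding intervals (`gene_id`,
#'   `chrom`, `start`, `end`), 0-based half-open.
#' @slot geneSets named list of two character vectors, `glycolytic` and
#'   `cholesterogenic`.
#' @slot truthLabels named character vector of planted subtypes per sample.
#' @slot config the `simConfig` list the cohort was generated from.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(expression = "ExpressionMatrix", clinical = "data.frame",
                 segments = "data.frame", mutations = "data.frame",
                 geneIntervals = "data.frame", geneSets = "list",
                 truthLabels = "character", config = "list"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  ids <- colnames(object@expression@values)
  if (!identical(object@clinical$sample_id, ids))
    msg <- c(msg, "clinical sample_id must align with expression columns")
  if (!identical(names(object@truthLabels), ids))
    msg <- c(msg, "truthLabels must be named by the expression samples")
  if (!all(object@truthLabels %in% .SUBTYPES))
    msg <- c(msg, "truthLabels must be metabolic subtype names")
  if (!all(c("glycolytic", "cholesterogenic") %in% names(object@geneSets)))
    msg <- c(msg, "geneSets must contain 'glycolytic' and 'cholesterogenic'")
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: resampling consensus clustering output
#'
#' @slot itemIds character vector of clustered item identifiers (genes, or
#'   samples for signature alignment).
#' @slot consensusMatrix item x item matrix in `[0, 1]`; entry `(i, j)` is the
#'   fraction of co-sampled resampling runs in which `i` and `j` fell in the
#'   same cluster.
#' @slot samplingCounts item x item integer matrix of co-sampling tallies.
#' @slot labels named integer vector: final cluster label per item, from
#'   Ward.D2 clustering of `1 - consensusMatrix`.
#' @slot k number of clusters.
#' @slot config the `clusterConfig` list used.
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(itemIds = "character", consensusMatrix = "matrix",
                 samplingCounts = "matrix", labels = "integer",
                 k = "integer", config = "list"))

setValidity("ConsensusResult", function(object) {
  M <- object@consensusMatrix
  msg <- character()
  if (!identical(dim(M), dim(object@samplingCounts)))
    msg <- c(msg, "consensusMatrix and samplingCounts dimensions differ")
  if (nrow(M) != length(object@itemIds))
    msg <- c(msg, "consensusMatrix dimension must match itemIds")
  if (any(M < -1e-12 | M > 1 + 1e-12))
    msg <- c(msg, "consensus values must lie in [0, 1]")
  if (max(abs(M - t(M))) > 1e-12)
    msg <- c(msg, "consensusMatrix must be symmetric")
  if (!identical(names(object@labels), object@itemIds))
    msg <- c(msg, "labels must be named by itemIds")
  if (length(msg)) msg else TRUE
})
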