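#' Accessors for ExpressionMatrix and cohort objects
#'
#' `exprValues` returns the raw numeric matrix, `scaleTag` the scale label,
#' `geneIds`/`sampleIds` the row/column identifiers. `consensusMatrix` and
#' `consensusLabels` extract the resampling consensus estimates and the final
#' cluster labels from a [ConsensusResult-class].
#'
#' @param x an object.
#' @return The corresponding component.
#' @name accessors
#' @aliases exprValues scaleTag geneIds sampleIds consensusMatrix
#'   consensusLabels cohortClinical cohortExpression truthLabels
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setGeneric("consensusLabels", function(x) standardGeneric("consensusLabels"))
#' @rdname accessors
#' @export
setGeneric("cohortExpression", function(x) standardGeneric("cohortExpression"))
#' @rdname accessors
#' @export
setGeneric("cohortClinical", function(x) standardGeneric("cohortClinical"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
setMethod("scaleTag", "ExpressionMatrix", function(x) x@scaleTag)
#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("consensusMatrix", "ConsensusResult", function(x) x@consensusMatrix)
#' @rdname accessors
setMethod("consensusLabels", "ConsensusResult", function(x) x@labels)
#' @rdname accessors
setMethod("cohortExpression", "SyntheticCohort", function(x) x@expression)
#' @rdname accessors
setMethod("cohortClinical", "SyntheticCohort", function(x) x@clinical)
#' @rdname accessors
setMethod("truthLabels", "SyntheticCohort", function(x) x@truthLabels)

#' @describeIn ExpressionMatrix-class matrix dimensions
#' @param x an `ExpressionMatrix`.
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' @describeIn ExpressionMatrix-class subset by gene and/or sample
#' @param i,j gene and sample indices (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; subsetting always returns an `ExpressionMatrix`.
#' @export
setMethod("[", "ExpressionMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("ExpressionMatrix", values = v, scaleTag = x@scaleTag)
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
              nrow(object@values), ncol(object@values), object@scaleTag))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(factor(object@truthLabels, levels = .SUBTYPES))
  cat(sprintf("SyntheticCohort: %d samples, %d genes, %d cohorts\n",
              ncol(object@expression@values), nrow(object@expression@values),
              length(unique(object@clinical$cohort))))
  cat("planted subtypes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("segments: %d, mutations: %d\n",
              nrow(object@segments), nrow(object@mutations)))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d items, k = %d, reps = %s\n",
              length(object@itemIds), object@k,
              as.character(object@config$reps %||% NA)))
  cat("cluster sizes:",
      paste(table(object@labels), collapse = ", "), "\n")
})
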