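`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Derive independent child seeds (< 2^31) from one master seed, so that
# expression, survival, CNV and mutation streams are individually reproducible.
.childSeeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))

.writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmtNum)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

.checkAligned <- function(matrixIds, clinicalIds, what = "clinical") {
  missing <- setdiff(matrixIds, clinicalIds)
  if (length(missing))
    .stopf("samples in matrix absent from %s: %s", what,
           paste(head(missing, 5), collapse = ", "))
}
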