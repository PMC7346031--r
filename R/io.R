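# Readers and writers for every external format the pipeline touches.
# All readers validate strictly and reject malformed input rather than
# silently coercing; every writer/reader pair round-trips exactly for
# strings and to < 1e-12 relative error for reals.
#
# Coordinate conventions: BED intervals are 0-based half-open; SEG segment
# coordinates are 1-based inclusive as emitted by segmentation tools and are
# converted to half-open only at overlap time (see mapEventsToGenes).

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Duplicated gene or sample identifiers, non-numeric cells and
#' ragged rows are rejected with an informative error.
#'
#' @param path path to a tab-separated file.
#' @param scaleTag scale of the stored values (default `"tpm"`).
#' @return An [ExpressionMatrix-class].
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, scaleTag = "tpm") {
  lines <- readLines(path)
  if (length(lines) < 2L) .stopf("expression file %s has no data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    .stopf("ragged expression file: row %d has %d fields, expected %d",
           which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  samples <- trimws(fields[[1]][-1])
  genes <- trimws(vapply(fields[-1], `[`, "", 1L))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    .stopf("duplicated gene row(s): %s", paste(dup, collapse = ", "))
  body <- vapply(fields[-1], function(f) {
    x <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(x))
      .stopf("non-numeric expression cell in gene row '%s'", trimws(f[1]))
    x
  }, numeric(length(samples)))
  values <- t(matrix(body, nrow = length(samples),
                     dimnames = list(samples, genes)))
  ExpressionMatrix(values, scaleTag)
}

#' Write an ExpressionMatrix to TSV
#'
#' @param em an [ExpressionMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(em, path) {
  v <- exprValues(em)
  lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], .fmtNum(v[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then members, tab-separated.
#' Empty members (e.g. from trailing tabs) are dropped with a warning, and
#' duplicate members within a line are de-duplicated with a warning.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors; the (otherwise ignored)
#'   description fields are kept in `attr(, "descriptions")`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) .stopf("GMT file %s is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    .stopf("GMT line %d has fewer than 3 fields", bad[1])
  sets <- lapply(fields, function(f) {
    members <- trimws(f[-(1:2)])
    if (any(!nzchar(members))) {
      .warnf("empty member(s) dropped from gene set '%s'", f[1])
      members <- members[nzchar(members)]
    }
    if (anyDuplicated(members)) {
      .warnf("duplicate member(s) de-duplicated in gene set '%s'", f[1])
      members <- unique(members)
    }
    if (!length(members)) .stopf("gene set '%s' has no members", f[1])
    members
  })
  names(sets) <- vapply(fields, `[`, "", 1L)
  attr(sets, "descriptions") <-
    setNames(vapply(fields, `[`, "", 2L), names(sets))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description fields (default `"na"`).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions") %||%
      setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read segmented copy-number calls (SEG format)
#'
#' Expects a header with columns `sample`, `chrom`, `loc.start`, `loc.end`,
#' `num.mark`, `seg.mean` and an optional `copy_status`. Coordinates are
#' 1-based inclusive. Rows with `start >= end` or non-positive probe counts
#' are rejected.
#'
#' @param path path to a SEG file.
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_probes`, `seg_mean`, `copy_status` (`NA` when the column is absent).
#' @export
readSeg <- function(path) {
  df <- .readTsv(path)
  need <- c("sample", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  if (!all(need %in% names(df)))
    .stopf("SEG file missing column(s): %s",
           paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(sample_id = trimws(as.character(df$sample)),
                    chrom = trimws(as.character(df$chrom)),
                    start = as.integer(df$loc.start),
                    end = as.integer(df$loc.end),
                    n_probes = as.integer(df$num.mark),
                    seg_mean = as.numeric(df$seg.mean),
                    copy_status = if ("copy_status" %in% names(df))
                      as.integer(df$copy_status) else NA_integer_,
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end) || anyNA(out$seg_mean))
    .stopf("SEG file contains non-numeric coordinates or segment means")
  bad <- which(out$start >= out$end)
  if (length(bad))
    .stopf("SEG row %d has start >= end (%d >= %d)", bad[1],
           out$start[bad[1]], out$end[bad[1]])
  bad <- which(is.na(out$n_probes) | out$n_probes < 1L)
  if (length(bad)) .stopf("SEG row %d has a non-positive probe count", bad[1])
  out
}

#' Write segments in SEG format
#' @param segments data.frame as returned by [readSeg()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSeg <- function(segments, path) {
  df <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                   loc.start = segments$start, loc.end = segments$end,
                   num.mark = segments$n_probes, seg.mean = segments$seg_mean)
  if (!all(is.na(segments$copy_status))) df$copy_status <- segments$copy_status
  .writeTsv(df, path)
}

#' Read gene coding intervals (BED format)
#'
#' Four-column BED: `chrom`, `start`, `end`, `name`; 0-based half-open.
#'
#' @param path path to a BED file (no header).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
readBed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) .stopf("BED file must have at least 4 columns")
  out <- data.frame(gene_id = trimws(as.character(df[[4]])),
                    chrom = trimws(as.character(df[[1]])),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end)
  if (length(bad)) .stopf("BED row %d has start >= end", bad[1])
  out
}

#' Write gene intervals in BED format
#' @param intervals data.frame as returned by [readBed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path) {
  lines <- paste(intervals$chrom, intervals$start, intervals$end,
                 intervals$gene_id, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Expects columns `sample_id`, `os_months`, `event`, `cohort`, `purity`,
#' `metastatic`. Overall survival must be non-negative and the event flag
#' 0/1; purity must lie in `[0, 1]` or be missing, the metastasis flag 0/1
#' or missing.
#'
#' @param path path to a tab-separated clinical file.
#' @param timeUnit `"months"` (default) or `"days"`; day-scale survival is
#'   converted to months by dividing by 30.44.
#' @return Validated data.frame.
#' @export
readClinical <- function(path, timeUnit = c("months", "days")) {
  timeUnit <- match.arg(timeUnit)
  df <- .readTsv(path)
  need <- c("sample_id", "os_months", "event", "cohort", "purity", "metastatic")
  if (!all(need %in% names(df)))
    .stopf("clinical file missing column(s): %s",
           paste(setdiff(need, names(df)), collapse = ", "))
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id))
    .stopf("duplicated sample_id in clinical file")
  df$os_months <- as.numeric(df$os_months)
  if (timeUnit == "days") df$os_months <- df$os_months / 30.44
  if (anyNA(df$os_months) || any(df$os_months < 0))
    .stopf("os_months must be non-negative for every sample")
  if (!all(df$event %in% c(0L, 1L))) .stopf("event must be 0 or 1")
  ok <- is.na(df$purity) | (df$purity >= 0 & df$purity <= 1)
  if (!all(ok)) .stopf("purity must lie in [0, 1] or be missing")
  if (!all(is.na(df$metastatic) | df$metastatic %in% c(0L, 1L)))
    .stopf("metastatic must be 0, 1 or missing")
  df[need]
}

#' Write a clinical table
#' @param clinical data.frame as returned by [readClinical()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(clinical, path) .writeTsv(clinical, path)

#' Read a simple per-sample mutation table
#'
#' Columns `gene`, `sample`, `class`, with class restricted to SNV or INDEL.
#'
#' @param path path to a tab-separated mutation file.
#' @return data.frame with columns `gene`, `sample`, `class`.
#' @export
readMutations <- function(path) {
  df <- .readTsv(path)
  need <- c("gene", "sample", "class")
  if (!all(need %in% names(df)))
    .stopf("mutation file missing column(s): %s",
           paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  if (nrow(df)) {
    df$gene <- trimws(as.character(df$gene))
    df$sample <- trimws(as.character(df$sample))
    df$class <- trimws(as.character(df$class))
    bad <- setdiff(unique(df$class), c("SNV", "INDEL"))
    if (length(bad))
      .stopf("mutation class must be SNV or INDEL, found: %s",
             paste(bad, collapse = ", "))
  }
  df
}

#' Write a mutation table
#' @param mutations data.frame as returned by [readMutations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMutations <- function(mutations, path) {
  if (!nrow(mutations))
    mutations <- data.frame(gene = character(), sample = character(),
                            class = character())
  .writeTsv(mutations[c("gene", "sample", "class")], path)
}
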