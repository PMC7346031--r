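# Copy-number event calling and subtype association. A segment is called
# amplified when it has >= 10 supporting probes, a segment mean strictly
# above 0.2 and (when an integer copy status is present) copy >= 3;
# deletions mirror this with mean < -0.2 and copy <= 1. Segments lacking a
# copy status are called on probes and segment mean alone. Called segments
# are mapped to gene coding intervals by >= 1 bp overlap.

#' Copy-number calling thresholds
#'
#' @param minProbes minimum supporting probes (default 10).
#' @param ampMean exclusive segment-mean threshold for amplification
#'   (default 0.2).
#' @param delMean exclusive segment-mean threshold for deletion (default
#'   -0.2).
#' @param ampCopy inclusive integer copy-status floor for amplification
#'   (default 3).
#' @param delCopy inclusive integer copy-status ceiling for deletion
#'   (default 1).
#' @return A list of class `cnvConfig`.
#' @export
cnvConfig <- function(minProbes = 10L, ampMean = 0.2, delMean = -0.2,
                      ampCopy = 3L, delCopy = 1L) {
  if (minProbes < 1L) .stopf("minProbes must be >= 1")
  if (!(ampMean > 0 && delMean < 0))
    .stopf("ampMean must be > 0 and delMean < 0")
  structure(list(minProbes = as.integer(minProbes), ampMean = ampMean,
                 delMean = delMean, ampCopy = as.integer(ampCopy),
                 delCopy = as.integer(delCopy)), class = "cnvConfig")
}

#' Call amplification and deletion events on segments
#'
#' Adds an `event_class` column (`"AMP"`, `"DEL"` or `NA` for uncalled) to
#' the segment table. Idempotent and order-invariant; tightening any
#' threshold can only reduce the number of called segments.
#'
#' @param segments data.frame as returned by [readSeg()].
#' @param config a [cnvConfig()].
#' @return The segment data.frame with an `event_class` column.
#' @export
callCnvEvents <- function(segments, config = cnvConfig()) {
  probesOk <- segments$n_probes >= config$minProbes
  copy <- segments$copy_status
  ampCopyOk <- is.na(copy) | copy >= config$ampCopy
  delCopyOk <- is.na(copy) | copy <= config$delCopy
  amp <- probesOk & segments$seg_mean > config$ampMean & ampCopyOk
  del <- probesOk & segments$seg_mean < config$delMean & delCopyOk
  segments$event_class <- ifelse(amp, "AMP", ifelse(del, "DEL", NA))
  segments
}

#' Map called copy-number segments to genes
#'
#' Emits one event per (gene, sample, class) for every called segment
#' overlapping a gene coding interval by at least 1 bp. SEG coordinates are
#' 1-based inclusive, BED intervals 0-based half-open; both are converted
#' to a common closed representation before the overlap query, so a segment
#' ending where a half-open interval starts does not overlap it.
#'
#' @param calledSegments output of [callCnvEvents()] (uncalled rows are
#'   ignored).
#' @param intervals gene intervals as returned by [readBed()].
#' @return data.frame with columns `gene_id`, `sample_id`, `event_class`,
#'   de-duplicated per (gene, sample, class).
#' @export
mapEventsToGenes <- function(calledSegments, intervals) {
  called <- calledSegments[!is.na(calledSegments$event_class), , drop = FALSE]
  empty <- data.frame(gene_id = character(), sample_id = character(),
                      event_class = character(), stringsAsFactors = FALSE)
  if (!nrow(called) || !nrow(intervals)) return(empty)
  segGr <- GenomicRanges::GRanges(
    called$chrom, IRanges::IRanges(called$start, called$end))
  geneGr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end))
  hits <- GenomicRanges::findOverlaps(segGr, geneGr)
  if (!length(hits)) return(empty)
  out <- data.frame(
    gene_id = intervals$gene_id[S4Vectors::subjectHits(hits)],
    sample_id = called$sample_id[S4Vectors::queryHits(hits)],
    event_class = called$event_class[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$gene_id, out$sample_id, out$event_class), , drop = FALSE]
}

#' Combine copy-number and mutation records into one event table
#'
#' @param cnvEvents data.frame from [mapEventsToGenes()].
#' @param mutations data.frame from [readMutations()] (columns `gene`,
#'   `sample`, `class`).
#' @return Long-format data.frame (`gene_id`, `sample_id`, `event_class`)
#'   suitable for oncoprint-style output and enrichment testing.
#' @export
combineGeneEvents <- function(cnvEvents, mutations = NULL) {
  out <- cnvEvents
  if (!is.null(mutations) && nrow(mutations)) {
    out <- rbind(out, data.frame(gene_id = mutations$gene,
                                 sample_id = mutations$sample,
                                 event_class = mutations$class,
                                 stringsAsFactors = FALSE))
  }
  unique(out)
}

#' Per-subtype event enrichment tests
#'
#' For every gene, event class and subtype, tests the 2x2 table (subtype
#' vs rest) x (event vs none) with the two-sided Fisher exact test, then
#' applies Benjamini-Hochberg adjustment jointly across the whole family
#' (all genes x classes x subtypes). A pooled `"ANY"` class combining all
#' event types per gene is included. Gene/class combinations with no
#' events are reported with `NA` p-values and excluded from the BH family.
#'
#' @param events long-format event table (`gene_id`, `sample_id`,
#'   `event_class`).
#' @param labels named subtype label per sample (all event samples must be
#'   labeled; samples without events but with labels count toward the
#'   margins).
#' @param genePanel optional gene subset to test (default: all genes in
#'   `events`).
#' @param includePooled include the pooled `"ANY"` class (default TRUE).
#' @return data.frame with columns `gene_id`, `event_class`, `subtype`,
#'   `n_event_in`, `n_event_out`, `n_in`, `n_out`, `p_value`, `p_adjusted`.
#' @export
testEventEnrichment <- function(events, labels, genePanel = NULL,
                                includePooled = TRUE) {
  if (is.null(names(labels))) .stopf("labels must be named by sample")
  labels <- vapply(labels, as.character, "")
  unlabeled <- setdiff(unique(events$sample_id), names(labels))
  if (length(unlabeled))
    .stopf("unlabeled sample(s) in events: %s",
           paste(head(unlabeled, 5), collapse = ", "))
  if (is.null(genePanel)) genePanel <- sort(unique(events$gene_id))
  classes <- sort(unique(events$event_class))
  samples <- names(labels)
  rows <- list()
  for (g in genePanel) {
    gEvents <- events[events$gene_id == g, , drop = FALSE]
    classSets <- lapply(setNames(classes, classes), function(cl)
      unique(gEvents$sample_id[gEvents$event_class == cl]))
    if (includePooled) classSets$ANY <- unique(gEvents$sample_id)
    for (cl in names(classSets)) {
      carriers <- samples %in% classSets[[cl]]
      for (st in unique(labels)) {
        inGroup <- labels == st
        tab <- c(a = sum(carriers & inGroup), b = sum(!carriers & inGroup),
                 c = sum(carriers & !inGroup), d = sum(!carriers & !inGroup))
        p <- if (sum(carriers) == 0) NA_real_ else
          fisherExact2x2(matrix(tab, 2, byrow = TRUE))$p.value
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, event_class = cl, subtype = st,
          n_event_in = tab[["a"]], n_event_out = tab[["c"]],
          n_in = sum(inGroup), n_out = sum(!inGroup), p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_adjusted[ok] <- bhAdjust(out$p_value[ok])
  rownames(out) <- NULL
  out
}

#' Association of a metabolic score with a target gene's events and level
#'
#' Compares the chosen metabolic score between samples carrying an event in
#' the target gene and samples without it (Wilcoxon rank-sum), and
#' correlates the score with the target gene's expression (Pearson).
#'
#' @param scores score frame from [computeMetabolicScores()].
#' @param em [ExpressionMatrix-class] containing the target gene.
#' @param events long-format event table.
#' @param targetGene gene identifier, e.g. `"MYC"` or `"TP53"`.
#' @param eventClass event class defining the carrier group (e.g. `"AMP"`).
#' @param score which score column to use (default `"chol_score"`).
#' @return List with elements `rankSum` (an `htest` plus group sizes) and
#'   `correlation` (an `htest` with the Pearson estimate).
#' @export
scoreGeneAssociation <- function(scores, em, events, targetGene, eventClass,
                                 score = c("chol_score", "gly_score")) {
  score <- match.arg(score)
  if (!targetGene %in% geneIds(em))
    .stopf("target gene '%s' not in the matrix", targetGene)
  carriers <- unique(events$sample_id[events$gene_id == targetGene &
                                        events$event_class == eventClass])
  has <- scores$sample_id %in% carriers
  if (sum(has) < 3L || sum(!has) < 3L)
    .stopf("fewer than 3 samples in a comparison group (%d vs %d)",
           sum(has), sum(!has))
  rs <- wilcoxonRankSum(scores[[score]][has], scores[[score]][!has])
  rs$n_carrier <- sum(has); rs$n_other <- sum(!has)
  expr <- exprValues(em)[targetGene, scores$sample_id]
  list(rankSum = rs, correlation = pearsonTest(scores[[score]], expr))
}
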