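toySeg <- function() readSeg(system.file("extdata", "toy_segments.seg",
                                         package = "MetaboSubtype"))

test_that("the toy segment panel is called exactly as designed", {
  calls <- callCnvEvents(toySeg())
  expect_identical(calls$event_class,
                   c("AMP", NA, NA, "AMP", NA, "AMP",
                     "DEL", NA, NA, "DEL", NA, "DEL"))
})

test_that("calling thresholds behave at their boundaries", {
  seg <- toySeg()
  # 9 probes fails, 10 passes (inclusive)
  expect_true(is.na(callCnvEvents(seg)$event_class[2]))
  # seg mean exactly 0.2 fails (exclusive), 0.21 passes
  expect_true(is.na(callCnvEvents(seg)$event_class[3]))
  # copy status 2 blocks AMP, missing copy status passes
  expect_true(is.na(callCnvEvents(seg)$event_class[5]))
  expect_identical(callCnvEvents(seg)$event_class[6], "AMP")
  # tightening any threshold only removes calls
  strict <- callCnvEvents(seg, cnvConfig(minProbes = 15, ampMean = 0.4,
                                         delMean = -0.4))
  base <- callCnvEvents(seg)
  called <- function(x) which(!is.na(x$event_class))
  expect_true(all(called(strict) %in% called(base)))
  # idempotent / order-invariant
  perm <- sample(nrow(seg))
  expect_identical(callCnvEvents(seg[perm, ])$event_class,
                   base$event_class[perm])
})

test_that("cnvConfig validates", {
  expect_error(cnvConfig(minProbes = 0), "minProbes")
  expect_error(cnvConfig(ampMean = -0.1), "ampMean")
})

test_that("segment-to-gene mapping honors the coordinate conventions", {
  # BED gene: 0-based half-open [1000, 2000) = 1-based positions 1001..2000
  bed <- data.frame(gene_id = "G", chrom = "chr1",
                    start = 1000L, end = 2000L, stringsAsFactors = FALSE)
  mkseg <- function(s, e) data.frame(
    sample_id = "S1", chrom = "chr1", start = s, end = e,
    n_probes = 50L, seg_mean = 0.5, copy_status = NA_integer_,
    event_class = "AMP", stringsAsFactors = FALSE)
  # segment ending at 1-based 1000 (the base before the gene): no overlap
  expect_identical(nrow(mapEventsToGenes(mkseg(900L, 1000L), bed)), 0L)
  # segment reaching 1-based 1001 (first gene base): 1 bp overlap
  hit <- mapEventsToGenes(mkseg(900L, 1001L), bed)
  expect_identical(hit$gene_id, "G")
  # segment starting at the last gene base (2000) overlaps
  expect_identical(nrow(mapEventsToGenes(mkseg(2000L, 2100L), bed)), 1L)
  # segment starting just past it does not
  expect_identical(nrow(mapEventsToGenes(mkseg(2001L, 2100L), bed)), 0L)
  # chromosome mismatch never overlaps
  seg <- mkseg(900L, 1500L); seg$chrom <- "chr2"
  expect_identical(nrow(suppressWarnings(mapEventsToGenes(seg, bed))), 0L)
  # uncalled segments are ignored
  seg <- mkseg(900L, 1500L); seg$event_class <- NA
  expect_identical(nrow(mapEventsToGenes(seg, bed)), 0L)
})

test_that("mapping de-duplicates per gene, sample and class", {
  bed <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                    start = c(0L, 5000L), end = c(1000L, 6000L),
                    stringsAsFactors = FALSE)
  seg <- data.frame(sample_id = "S1", chrom = "chr1",
                    start = c(1L, 500L), end = c(900L, 950L),
                    n_probes = 50L, seg_mean = 0.5,
                    copy_status = NA_integer_, event_class = "AMP",
                    stringsAsFactors = FALSE)
  out <- mapEventsToGenes(seg, bed)
  expect_identical(nrow(out), 1L)
  expect_identical(out$gene_id, "G1")
})

test_that("combineGeneEvents merges CNV and mutation records", {
  cnv <- data.frame(gene_id = "MYC", sample_id = "S1", event_class = "AMP",
                    stringsAsFactors = FALSE)
  mut <- data.frame(gene = c("TP53", "MYC"), sample = c("S1", "S2"),
                    class = c("SNV", "INDEL"), stringsAsFactors = FALSE)
  out <- combineGeneEvents(cnv, mut)
  expect_identical(nrow(out), 3L)
  expect_setequal(out$event_class, c("AMP", "SNV", "INDEL"))
  expect_identical(combineGeneEvents(cnv, NULL), cnv)
})

test_that("enrichment agrees with stats::fisher.test and is BH-adjusted", {
  labels <- setNames(rep(c("glycolytic", "quiescent"), c(20, 30)),
                     sprintf("S%02d", 1:50))
  events <- data.frame(
    gene_id = "MYC", sample_id = sprintf("S%02d", c(1:10, 21:23)),
    event_class = "AMP", stringsAsFactors = FALSE)
  out <- testEventEnrichment(events, labels, includePooled = FALSE)
  row <- out[out$subtype == "glycolytic", ]
  ref <- stats::fisher.test(matrix(c(10, 10, 3, 27), 2, byrow = TRUE))
  expect_equal(row$p_value, ref$p.value, tolerance = 1e-12)
  expect_identical(row$n_event_in, 10L)
  expect_identical(row$n_in, 20L)
  expect_equal(out$p_adjusted, MetaboSubtype::bhAdjust(out$p_value))
})

test_that("enrichment includes the pooled ANY class and NA for empty combos", {
  labels <- setNames(rep(c("a", "b"), each = 5), sprintf("S%d", 1:10))
  events <- data.frame(gene_id = c("G1", "G1"), sample_id = c("S1", "S2"),
                       event_class = c("AMP", "DEL"),
                       stringsAsFactors = FALSE)
  out <- testEventEnrichment(events, labels)
  expect_true("ANY" %in% out$event_class)
  any_a <- out[out$event_class == "ANY" & out$subtype == "a", ]
  expect_identical(any_a$n_event_in, 2L)
  expect_error(testEventEnrichment(
    data.frame(gene_id = "G", sample_id = "SX", event_class = "AMP"),
    labels), "unlabeled")
})

test_that("scoreGeneAssociation compares carriers and correlates expression", {
  set.seed(20)
  em <- makeStdMatrix(5, 30, genes = c("MYC", paste0("G", 1:4)))
  scores <- data.frame(sample_id = sampleIds(em),
                       gly_score = rnorm(30), chol_score = rnorm(30))
  events <- data.frame(gene_id = "MYC",
                       sample_id = sampleIds(em)[1:8],
                       event_class = "AMP", stringsAsFactors = FALSE)
  res <- scoreGeneAssociation(scores, em, events, "MYC", "AMP")
  expect_identical(res$rankSum$n_carrier, 8L)
  ref <- stats::wilcox.test(scores$chol_score[1:8], scores$chol_score[9:30],
                            exact = TRUE)
  expect_equal(res$rankSum$p.value, ref$p.value, tolerance = 1e-12)
  refCor <- stats::cor.test(scores$chol_score,
                            exprValues(em)["MYC", ])
  expect_equal(res$correlation$p.value, refCor$p.value, tolerance = 1e-10)
  expect_error(scoreGeneAssociation(scores, em, events[1:2, ], "MYC", "AMP"),
               "fewer than 3")
  expect_error(scoreGeneAssociation(scores, em, events, "NOPE", "AMP"),
               "not in the matrix")
})
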