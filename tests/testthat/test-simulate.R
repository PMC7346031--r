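test_that("simConfig validates its inputs", {
  expect_s3_class(simConfig(), "simConfig")
  expect_error(simConfig(nSamples = 0), "positive")
  expect_error(simConfig(subtypeProportions = c(quiescent = 0.5,
    glycolytic = 0.5, cholesterogenic = 0.5, mixed = 0.5)), "sum to 1")
  expect_error(simConfig(blockCorrelation = 1), "blockCorrelation")
  expect_error(simConfig(censoringRate = 1), "censoringRate")
  expect_error(simConfig(hazardRatios = c(quiescent = -1, glycolytic = 1,
    cholesterogenic = 2, mixed = 1.6)), "hazardRatios")
  expect_error(simConfig(cohortOffsets = c(A = 0)), "cohort")
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  a <- simulateCohort(simConfig(nSamples = 50, seed = 7))
  b <- simulateCohort(simConfig(nSamples = 50, seed = 7))
  d <- simulateCohort(simConfig(nSamples = 50, seed = 8))
  expect_identical(exprValues(cohortExpression(a)),
                   exprValues(cohortExpression(b)))
  expect_identical(cohortClinical(a), cohortClinical(b))
  expect_identical(truthLabels(a), truthLabels(b))
  expect_false(identical(truthLabels(a), truthLabels(d)) &&
                 identical(exprValues(cohortExpression(a)),
                           exprValues(cohortExpression(d))))
})

test_that("child seed derivation is deterministic and leaves the RNG alone", {
  set.seed(123); before <- .Random.seed
  s1 <- MetaboSubtype:::.childSeeds(5L, 5L)
  expect_identical(before, .Random.seed)
  s2 <- MetaboSubtype:::.childSeeds(5L, 5L)
  expect_identical(s1, s2)
  expect_false(identical(s1, MetaboSubtype:::.childSeeds(6L, 5L)))
  expect_true(all(s1 >= 1 & s1 < 2^31))
})

test_that("expression is TPM: non-negative columns summing to 1e6", {
  v <- exprValues(cohortExpression(smallCohort()))
  expect_true(all(v >= 0))
  expect_equal(unname(colSums(v)), rep(1e6, ncol(v)), tolerance = 1e-9)
  expect_identical(scaleTag(cohortExpression(smallCohort())), "tpm")
})

test_that("planted proportions, cohorts and purity match the configuration", {
  cohort <- simulateCohort(simConfig(nSamples = 4000, seed = 99))
  tab <- table(truthLabels(cohort)) / 4000
  props <- simConfig()$subtypeProportions
  expect_true(all(abs(tab[names(props)] - props) < 0.03))
  cl <- cohortClinical(cohort)
  expect_true(abs(mean(cl$cohort == "TCGA") - 0.64) < 0.03)
  # Beta(4, 2) purity: a small but non-trivial tail below the 0.30 filter
  lowFrac <- mean(cl$purity < 0.30)
  expect_gt(lowFrac, 0.005)
  expect_lt(lowFrac, 0.08)
  expect_true(abs(mean(cl$event == 0) - 0.3) < 0.05)
})

test_that("planted block shifts act on the intended samples", {
  cohort <- simulateCohort(simConfig(nSamples = 800, seed = 13,
                                     blockCorrelation = 0))
  em <- cohortExpression(cohort)
  z <- batchCorrect(logTransform(em),
                    setNames(cohortClinical(cohort)$cohort,
                             cohortClinical(cohort)$sample_id))
  labels <- truthLabels(cohort)
  glyMean <- colMeans(exprValues(z)[cohort@geneSets$glycolytic, ])
  cholMean <- colMeans(exprValues(z)[cohort@geneSets$cholesterogenic, ])
  glyActive <- labels %in% c("glycolytic", "mixed")
  cholActive <- labels %in% c("cholesterogenic", "mixed")
  expect_gt(mean(glyMean[glyActive]) - mean(glyMean[!glyActive]), 0.5)
  expect_gt(mean(cholMean[cholActive]) - mean(cholMean[!cholActive]), 0.5)
})

test_that("within-phenotype residual correlation tracks blockCorrelation", {
  withinCor <- function(rho) {
    cohort <- simulateCohort(simConfig(nSamples = 1200, seed = 31,
                                       blockCorrelation = rho,
                                       cohortOffsets = c(TCGA = 0),
                                       cohortProportions = c(TCGA = 1)))
    v <- log10(exprValues(cohortExpression(cohort)) + 1)
    quiescent <- names(truthLabels(cohort))[truthLabels(cohort) == "quiescent"]
    gly <- v[cohort@geneSets$glycolytic, quiescent]
    cm <- cor(t(gly))
    mean(cm[upper.tri(cm)])
  }
  expect_lt(abs(withinCor(0.5) - 0.5), 0.1)
  expect_lt(withinCor(0), 0.15)
})

test_that("survival hazards order median survival as configured", {
  cohort <- simulateCohort(simConfig(nSamples = 5000, seed = 77,
                                     censoringRate = 0))
  cl <- cohortClinical(cohort)
  labels <- truthLabels(cohort)
  med <- tapply(cl$os_months, labels, median)
  expect_gt(med[["glycolytic"]], med[["quiescent"]])
  expect_gt(med[["quiescent"]], med[["cholesterogenic"]])
  # exponential with HR 1: median ~ baselineMedianMonths
  expect_lt(abs(med[["glycolytic"]] - 36) / 36, 0.15)
})

test_that("MYC amplification and TP53 deletion are subtype-enriched", {
  cohort <- simulateCohort(simConfig(nSamples = 3000, seed = 55))
  segs <- cohort@segments
  labels <- truthLabels(cohort)
  ampSamples <- unique(segs$sample_id[segs$chrom == "chr8" &
                                        segs$seg_mean > 0.2])
  ampRate <- tapply(names(labels) %in% ampSamples, labels, mean)
  expect_gt(ampRate[["cholesterogenic"]], ampRate[["quiescent"]] + 0.15)
})

test_that("writeCohort emits files every reader accepts and round-trips", {
  dir <- withr::local_tempdir()
  cohort <- smallCohort()
  paths <- writeCohort(cohort, dir)
  expect_true(all(file.exists(paths)))
  em <- readExpression(paths[["expression"]])
  expect_equal(exprValues(em), exprValues(cohortExpression(cohort)),
               tolerance = 1e-12)
  cl <- readClinical(paths[["clinical"]])
  expect_equal(cl, cohortClinical(cohort))
  sets <- readGmt(paths[["gene_sets"]])
  expect_identical(sets[["GLYCOLYSIS"]], cohort@geneSets$glycolytic)
  expect_identical(unname(attr(sets, "descriptions")),
                   c("glycolytic", "cholesterogenic"))
  seg <- readSeg(paths[["segments"]])
  expect_equal(seg, cohort@segments)
  bed <- readBed(paths[["bed"]])
  expect_equal(bed, cohort@geneIntervals)
  expect_equal(readMutations(paths[["mutations"]]), cohort@mutations)
})

test_that("gene layout covers all genes with valid half-open intervals", {
  cohort <- smallCohort()
  lay <- cohort@geneIntervals
  expect_setequal(lay$gene_id, geneIds(cohortExpression(cohort)))
  expect_true(all(lay$start < lay$end))
  expect_true(all(c("MYC", "TP53", "MPC1", "MPC2") %in% lay$gene_id))
})
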