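test_that("summarizeGeneClusters computes fractions over annotated members", {
  labels <- setNames(c(1L, 1L, 1L, 1L, 2L, 2L, 3L),
                     c("g1", "g2", "g3", "x1", "c1", "c2", "x2"))
  s <- summarizeGeneClusters(labels, glyGenes = c("g1", "g2", "g3"),
                             cholGenes = c("c1", "c2"))
  expect_identical(s$cluster_id, c(1L, 2L, 3L))
  expect_identical(s$n_members, c(4L, 2L, 1L))
  # cluster 1: 3 gly of 3 annotated (x1 unannotated, ignored)
  expect_equal(s$frac_gly, c(1, 0, 0))
  expect_equal(s$frac_chol, c(0, 1, 0))
  # cluster with no annotated members gets 0, not NaN
  expect_equal(s$homogeneity[3], 0)
  expect_error(summarizeGeneClusters(unname(labels), "g1", "c1"), "named")
})

test_that("core thresholds are exclusive at exactly 0.30 and 0.90", {
  mk <- function(fracGly, fracChol) data.frame(
    cluster_id = 1:2, n_members = c(10L, 10L), n_annotated = c(10L, 10L),
    n_gly = c(round(10 * fracGly), 0L),
    n_chol = c(0L, round(10 * fracChol)),
    frac_gly = c(fracGly, 0), frac_chol = c(0, fracChol),
    homogeneity = c(fracGly, fracChol))
  labels <- setNames(rep(1:2, each = 10), paste0("g", 1:20))
  # frac_gly exactly 0.30 does not qualify; 0.31 does
  expect_error(selectCoreClusters(mk(0.30, 0.95), labels), "glycolytic")
  expect_identical(selectCoreClusters(mk(0.31, 0.95),
                                      labels)$glycolytic$cluster_id, 1L)
  # frac_chol exactly 0.90 does not qualify; 0.91 does
  expect_error(selectCoreClusters(mk(0.5, 0.90), labels), "cholesterogenic")
  expect_identical(selectCoreClusters(mk(0.5, 0.91),
                                      labels)$cholesterogenic$cluster_id, 2L)
})

test_that("core selection prefers homogeneity, then size, then lowest id", {
  s <- data.frame(cluster_id = 1:3, n_members = c(5L, 8L, 8L),
                  n_annotated = c(5L, 8L, 8L), n_gly = c(3L, 4L, 4L),
                  n_chol = c(0L, 0L, 0L), frac_gly = c(0.6, 0.5, 0.5),
                  frac_chol = 0, homogeneity = c(0.6, 0.5, 0.5))
  labels <- setNames(c(rep(1L, 5), rep(2L, 8), rep(3L, 8)), paste0("g", 1:21))
  pick <- MetaboSubtype:::.pickCore(s, "frac_gly", 0.30, "glycolytic")
  expect_identical(pick$cluster_id, 1L)       # highest fraction wins
  s$frac_gly <- c(0.5, 0.5, 0.5)
  pick <- MetaboSubtype:::.pickCore(s, "frac_gly", 0.30, "glycolytic")
  expect_identical(pick$cluster_id, 2L)       # tie: larger cluster
  s$n_members <- c(8L, 8L, 8L)
  pick <- MetaboSubtype:::.pickCore(s, "frac_gly", 0.30, "glycolytic")
  expect_identical(pick$cluster_id, 1L)       # tie: lowest id
})

test_that("computeMetabolicScores takes per-sample medians and checks coverage", {
  v <- rbind(A = c(1, -1), B = c(3, 0), C = c(5, 2), D = c(0, 10))
  colnames(v) <- c("S1", "S2")
  em <- ExpressionMatrix(v, "standardized")
  sc <- computeMetabolicScores(em, coreGly = c("A", "B", "C"),
                               coreChol = c("C", "D"))
  expect_identical(sc$sample_id, c("S1", "S2"))
  expect_equal(sc$gly_score, c(3, 0))               # odd count: middle value
  expect_equal(sc$chol_score, c(2.5, 6))            # even count: midpoint
  # half present is allowed, less than half is not
  expect_silent(computeMetabolicScores(em, c("A", "ZZ"), c("C", "D")))
  expect_error(computeMetabolicScores(em, c("A", "ZZ", "YY"), c("C", "D")),
               "50% of core glycolytic")
  # list form from selectCoreClusters is accepted
  sc2 <- computeMetabolicScores(em, list(genes = c("A", "B", "C")),
                                list(genes = c("C", "D")))
  expect_equal(sc2, sc)
})

test_that("quadrant rule boundary: both scores zero is quiescent", {
  lab <- assignSubtypes(c(0, 1e-12, 0, 1e-12, -1),
                        c(0, 0, 1e-12, 1e-12, -1))
  expect_identical(as.character(lab),
                   c("quiescent", "glycolytic", "cholesterogenic", "mixed",
                     "quiescent"))
  expect_identical(levels(lab),
                   c("quiescent", "glycolytic", "cholesterogenic", "mixed"))
  df <- data.frame(sample_id = c("a", "b"), gly_score = c(0.2, -0.2),
                   chol_score = c(-0.3, 0.3))
  out <- assignSubtypes(df)
  expect_identical(as.character(out$subtype),
                   c("glycolytic", "cholesterogenic"))
  expect_error(assignSubtypes(c(NA, 1), c(0, 0)), "finite")
})

test_that("classifySamples recovers planted block structure", {
  d <- makeBlockDataset(glyCounts = c(8, 0, 2, 2, 1),
                        cholCounts = c(2, 10, 2, 2, 3), nSamples = 10)
  res <- classifySamples(d$em, d$glyGenes, d$cholGenes,
                         clusterConfig(k = 5, reps = 10, pItem = 1, seed = 2))
  expect_identical(nrow(res$clusterSummary), 5L)
  expect_equal(res$cores$glycolytic$fraction, 0.8)
  expect_equal(res$cores$cholesterogenic$fraction, 1)
  expect_identical(sort(res$cores$cholesterogenic$genes),
                   sort(grep("^B2_", c(d$glyGenes, d$cholGenes),
                             value = TRUE)))
  expect_true(all(res$subtypes$subtype %in%
                    c("quiescent", "glycolytic", "cholesterogenic", "mixed")))
  expect_error(classifySamples(d$em, "nope", "nada", clusterConfig(k = 5)),
               "fewer metabolic genes")
})

test_that("runPanCancer omits small or heterogeneous datasets with reasons", {
  good <- makeBlockDataset(glyCounts = c(8, 0, 2, 2, 1),
                           cholCounts = c(2, 10, 2, 2, 3), nSamples = 12)
  small <- makeBlockDataset(glyCounts = c(8, 0, 2, 2, 1),
                            cholCounts = c(2, 10, 2, 2, 3), nSamples = 4)
  # best gly core 37/50 = 0.74: below the 0.75 homogeneity floor
  lowH <- makeBlockDataset(glyCounts = c(37, 0, 5, 2, 1),
                           cholCounts = c(13, 10, 5, 3, 3), nSamples = 12)
  # 36/48 = 0.75 exactly: inclusive floor retains it
  atH <- makeBlockDataset(glyCounts = c(36, 0, 5, 2, 1),
                          cholCounts = c(12, 10, 5, 3, 3), nSamples = 12)
  cfg <- clusterConfig(k = 5, reps = 5, pItem = 1, seed = 4)
  datasets <- lapply(list(good = good, small = small, lowH = lowH, atH = atH),
                     function(d) list(em = d$em, glyGenes = d$glyGenes,
                                      cholGenes = d$cholGenes))
  res <- runPanCancer(datasets, config = cfg, minSamples = 10L)
  expect_setequal(names(res$subtypes), c("good", "atH"))
  expect_setequal(res$omitted$dataset, c("small", "lowH"))
  expect_match(res$omitted$reason[res$omitted$dataset == "small"],
               "only 4 samples")
  expect_match(res$omitted$reason[res$omitted$dataset == "lowH"],
               "homogeneity below")
})
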