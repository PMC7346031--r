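test_that("fisherExact2x2 matches stats::fisher.test on all small tables", {
  for (n in 0:10) {
    # enumerate a spread of tables with total n
    set.seed(n)
    for (rep in 1:20) {
      cells <- as.vector(stats::rmultinom(1, n, prob = rep(0.25, 4)))
      tab <- matrix(cells, 2, 2)
      ours <- fisherExact2x2(tab)$p.value
      if (n == 0) { expect_equal(ours, 1); next }
      ref <- stats::fisher.test(tab)$p.value
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  }
})

test_that("fisherExact2x2 rejects bad tables and reports the odds ratio", {
  expect_error(fisherExact2x2(matrix(1:6, 2, 3)), "2x2")
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "2x2")
  expect_error(fisherExact2x2(matrix(c(0.5, 1, 1, 1), 2)), "2x2")
  ht <- fisherExact2x2(matrix(c(6, 2, 2, 6), 2))
  expect_equal(unname(ht$statistic), 9)  # sample odds ratio (6*6)/(2*2)
})

test_that("bhAdjust matches p.adjust(\"BH\") including NA handling", {
  set.seed(1)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-14)
  }
  p <- c(0.01, NA, 0.04, NA, 0.9)
  expect_equal(bhAdjust(p), stats::p.adjust(p, "BH"))
  expect_identical(bhAdjust(c(NA_real_, NA_real_)), c(NA_real_, NA_real_))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # properties: bounded, idempotent, never below raw p
  p <- runif(30)
  a <- bhAdjust(p)
  expect_true(all(a >= p & a <= 1))
  expect_equal(bhAdjust(a), bhAdjust(bhAdjust(a)))
})

test_that("spearmanTest is exact for n <= 9 and matches cor.test", {
  set.seed(2)
  for (n in c(4, 6, 8)) {
    x <- rnorm(n); y <- rnorm(n)
    ours <- spearmanTest(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = TRUE))
    expect_equal(unname(ours$estimate), unname(ref$estimate),
                 tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    expect_match(ours$method, "exact")
  }
})

test_that("spearmanTest uses the t approximation above n = 9", {
  set.seed(3)
  x <- rnorm(40); y <- x + rnorm(40)
  ours <- spearmanTest(x, y)
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((40 - 2) / (1 - rho^2))
  expect_equal(ours$p.value, 2 * pt(-abs(tstat), 38), tolerance = 1e-12)
  expect_match(ours$method, "approximation")
  # ties are handled through mid-ranks
  xt <- c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  yt <- xt + rnorm(12)
  reft <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman"))
  expect_equal(unname(spearmanTest(xt, yt)$estimate),
               unname(reft$estimate), tolerance = 1e-12)
  expect_true(is.na(spearmanTest(rep(1, 12), rnorm(12))$p.value))
  expect_error(spearmanTest(1:3, 1:4), "equal-length")
})

test_that("pearsonTest matches cor.test", {
  set.seed(4)
  for (n in c(5, 20, 100)) {
    x <- rnorm(n); y <- x * 0.3 + rnorm(n)
    ours <- pearsonTest(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(unname(ours$estimate), unname(ref$estimate),
                 tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
  expect_true(is.na(pearsonTest(rep(1, 10), rnorm(10))$p.value))
})

test_that("wilcoxonRankSum matches wilcox.test exactly and approximately", {
  set.seed(5)
  # exact branch: no ties, small groups
  for (rep in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:10, 1))
    ours <- wilcoxonRankSum(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_match(ours$method, "exact")
  }
  # normal approximation with ties and continuity correction
  a <- c(1, 2, 2, 3, 5, 6, 6, 8, 9, 10, 11, 12)
  b <- c(2, 3, 3, 4, 6, 7, 8, 8, 13, 14, 15, 16, 17, 18)
  ours <- wilcoxonRankSum(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  expect_match(ours$method, "approximation")
  # large groups take the approximation even without ties
  set.seed(6)
  a <- rnorm(25); b <- rnorm(30)
  expect_match(wilcoxonRankSum(a, b)$method, "approximation")
  expect_error(wilcoxonRankSum(numeric(), 1:3), "non-empty")
})

test_that("hypergeomEnrich matches phyper and hand values", {
  # drawing all 5 marked of 10: p = 1 / choose(10, 5)
  expect_equal(hypergeomEnrich(5, 5, 10, 5)$p.value, 1 / choose(10, 5),
               tolerance = 1e-14)
  set.seed(7)
  for (rep in 1:30) {
    N <- sample(10:200, 1); K <- sample(1:N, 1); d <- sample(1:N, 1)
    k <- sample(0:min(K, d), 1)
    ours <- hypergeomEnrich(k, K, N, d)$p.value
    ref <- stats::phyper(k - 1, K, N - K, d, lower.tail = FALSE)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  expect_error(hypergeomEnrich(6, 5, 10, 5), "inconsistent")
})

test_that("enrichGeneSets tests each set against the universe", {
  universe <- paste0("G", 1:100)
  sets <- list(A = paste0("G", 1:10), B = paste0("G", 11:40),
               C = paste0("G", 200:210))  # outside the universe
  hits <- paste0("G", c(1:8, 50:61))
  out <- enrichGeneSets(hits, sets, universe)
  expect_identical(out$overlap, c(8L, 0L, 0L))
  expect_identical(out$set_size, c(10L, 30L, 0L))
  refA <- stats::phyper(7, 10, 90, 20, lower.tail = FALSE)
  expect_equal(out$p_value[1], refA, tolerance = 1e-12)
  expect_true(is.na(out$p_value[3]))
  expect_equal(out$p_adjusted, bhAdjust(out$p_value))
})
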