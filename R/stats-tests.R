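# Exact and asymptotic test primitives used throughout the analysis:
# two-sided Fisher exact test, Benjamini-Hochberg step-up adjustment,
# Spearman and Pearson correlation tests, Wilcoxon rank-sum, and the
# hypergeometric upper-tail enrichment test. Table probabilities are
# computed from log binomial coefficients; base distribution functions
# (pt, pnorm, pwilcox) supply the reference distributions. Every exact
# routine is checked in the test suite against brute-force enumeration.

.htest <- function(statistic, p, method, estimate = NULL, n = NA_integer_,
                   parameter = NULL) {
  out <- list(statistic = statistic, p.value = p, method = method,
              estimate = estimate, parameter = parameter, n = n,
              data.name = "x")
  class(out) <- "htest"
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by summation: the probabilities of all tables with the
#' observed margins whose hypergeometric probability does not exceed the
#' observed table's (within a 1e-7 relative tolerance, the usual guard
#' against ties lost to floating point).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return An `htest` with the sample odds ratio as estimate.
#' @examples
#' fisherExact2x2(matrix(c(2, 0, 0, 2), 2))$p.value  # 1/3
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) ||
      any(table != round(table)) || any(!is.finite(table)))
    .stopf("need a 2x2 table of non-negative integers")
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); n <- sum(table)
  if (n == 0L) return(.htest(NA_real_, 1, "Fisher exact test (two-sided)"))
  support <- max(0L, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  pObs <- logp[support == a]
  p <- sum(exp(logp[logp <= pObs + log(1 + 1e-7)]))
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  .htest(c(`odds ratio` = or), min(p, 1),
         "Fisher exact test (two-sided)", n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj_(i) = min(1, min_{j >= i} (n / j) * p_(j))` over the ascending
#' order statistics. Monotone in the input order statistics, bounded by 1,
#' idempotent, and never below the raw p-value. `NA`s are passed through
#' and excluded from the family size.
#'
#' @param p numeric vector of p-values.
#' @return Vector of adjusted p-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) .stopf("p-values must lie in [0, 1]")
  n <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(n / seq(n, 1) * pv[o]))
  out[ok][o] <- adj
  out
}

# all permutations of 1..n, one per row (exact small-sample null)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman rank correlation test
#'
#' Rho is the Pearson correlation of mid-ranks (which applies the standard
#' tie correction). For `n <= 9` the p-value is exact, by full enumeration
#' of the `n!` rank permutations; above that a t approximation on `n - 2`
#' degrees of freedom is used.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return An `htest` with estimate `rho`.
#' @export
spearmanTest <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) .stopf("need equal-length vectors, n >= 3")
  if (anyNA(x) || anyNA(y)) .stopf("missing values not supported")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(.htest(c(rho = NA_real_), NA_real_,
                  "Spearman rank correlation", n = n))
  rho <- cor(rx, ry)
  if (n <= 9L) {
    perms <- .permutations(n)
    rhoAll <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation (exact permutation)"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    method <- "Spearman rank correlation (t approximation)"
  }
  .htest(c(rho = rho), min(p, 1), method, estimate = c(rho = rho), n = n)
}

#' Pearson correlation test
#'
#' Two-sided t-test of zero correlation on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return An `htest` with estimate `r`.
#' @export
pearsonTest <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) .stopf("need equal-length vectors, n >= 3")
  if (anyNA(x) || anyNA(y)) .stopf("missing values not supported")
  if (sd(x) == 0 || sd(y) == 0)
    return(.htest(c(r = NA_real_), NA_real_, "Pearson correlation", n = n))
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  .htest(c(t = tstat), min(p, 1), "Pearson correlation",
         estimate = c(r = r), n = n)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. Exact (via the null distribution of the Mann-Whitney U
#' statistic, doubling the smaller tail) when there are no ties and the
#' smaller group has at most `exactLimit` observations; otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exactLimit exact-branch size limit for the smaller group
#'   (default 10).
#' @return An `htest` with the U statistic.
#' @examples
#' wilcoxonRankSum(1:3, 4:6)$p.value  # 0.1
#' @export
wilcoxonRankSum <- function(a, b, exactLimit = 10L) {
  if (!length(a) || !length(b)) .stopf("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) .stopf("missing values not supported")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && min(na, nb) <= exactLimit) {
    lo <- stats::pwilcox(U, na, nb)
    hi <- 1 - stats::pwilcox(U - 1, na, nb)
    p <- min(1, 2 * min(lo, hi))
    method <- "Wilcoxon rank-sum (exact)"
  } else {
    mu <- na * nb / 2
    tieTab <- table(r)
    sigma2 <- na * nb / 12 *
      (na + nb + 1 - sum(tieTab^3 - tieTab) / ((na + nb) * (na + nb - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Wilcoxon rank-sum (normal approximation)"
  }
  .htest(c(U = U), p, method, n = na + nb)
}

#' Hypergeometric upper-tail enrichment test
#'
#' `P(X >= hits)` when drawing `drawSize` items from a universe of
#' `universeSize` containing `setSize` marked items. Computed from log
#' binomial coefficients.
#'
#' @param hits observed overlap count.
#' @param setSize number of marked items in the universe.
#' @param universeSize universe size.
#' @param drawSize number of items drawn.
#' @return An `htest`.
#' @examples
#' hypergeomEnrich(5, 5, 10, 5)$p.value  # 1/choose(10, 5)
#' @export
hypergeomEnrich <- function(hits, setSize, universeSize, drawSize) {
  if (any(c(hits, setSize, universeSize, drawSize) < 0) ||
      setSize > universeSize || drawSize > universeSize ||
      hits > min(setSize, drawSize))
    .stopf("inconsistent hypergeometric counts")
  k <- hits:min(setSize, drawSize)
  logp <- lchoose(setSize, k) + lchoose(universeSize - setSize, drawSize - k) -
    lchoose(universeSize, drawSize)
  .htest(c(hits = hits), min(1, sum(exp(logp))),
         "hypergeometric upper-tail enrichment", n = universeSize)
}

#' Hypergeometric enrichment of a gene list against gene sets
#'
#' Tests each set for over-representation in `hits`, with the tested
#' transcriptome as the universe, and BH-adjusts across sets.
#'
#' @param hits character vector of genes of interest.
#' @param sets named list of gene sets.
#' @param universe character vector of all tested genes.
#' @return data.frame with per-set overlap counts, raw and adjusted p.
#' @export
enrichGeneSets <- function(hits, sets, universe) {
  hits <- intersect(hits, universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(hits, s))
    p <- if (length(s)) hypergeomEnrich(ov, length(s), length(universe),
                                        length(hits))$p.value else NA_real_
    data.frame(set = nm, set_size = length(s), overlap = ov, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bhAdjust(out$p_value)
  out
}
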