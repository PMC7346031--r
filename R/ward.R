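# Agglomerative Ward.D2 clustering, written out explicitly so that the
# merge criterion and tie-breaking are fully specified: squared Euclidean
# distances updated by the Lance-Williams recurrence
#   d2(k, i+j) = [(n_i+n_k) d2(k,i) + (n_j+n_k) d2(k,j) - n_k d2(i,j)]
#                / (n_i + n_j + n_k)
# with recorded merge heights sqrt(d2) (the Ward.D2 convention, matching
# stats::hclust(method = "ward.D2")). Ties on the minimal merge cost are
# broken by the lexicographically smallest active position pair, so the
# result is deterministic given the input row order.

.wardFromD2 <- function(D2, sizes, labels) {
  n <- nrow(D2)
  active <- rep(TRUE, n)
  clusterId <- -seq_len(n)          # hclust convention: negatives = leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(D2) <- Inf
  for (step in seq_len(n - 1L)) {
    m <- min(D2[active, active])
    cand <- which(D2 == m & outer(active, active, "&"), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    merge[step, ] <- sort(c(clusterId[i], clusterId[j]))
    height[step] <- sqrt(m)
    ni <- sizes[i]; nj <- sizes[j]
    others <- which(active); others <- others[others != i & others != j]
    if (length(others)) {
      nk <- sizes[others]
      newd <- ((ni + nk) * D2[i, others] + (nj + nk) * D2[j, others] -
                 nk * D2[i, j]) / (ni + nj + nk)
      D2[i, others] <- newd
      D2[others, i] <- newd
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
    D2[j, ] <- Inf; D2[, j] <- Inf; D2[i, i] <- Inf
    clusterId[i] <- step
  }
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) ord <<- c(ord, -node)
    else { walk(merge[node, 1]); walk(merge[node, 2]) }
  }
  if (n > 1L) walk(n - 1L)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "ward.D2",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Ward.D2 hierarchical clustering of points
#'
#' Builds the full Ward.D2 hierarchy on Euclidean distances between the
#' rows of `x`. Returns a standard `hclust` object (cut it with
#' [stats::cutree()] or [wardHclust()]). Merge heights are guaranteed
#' non-decreasing; ties are broken deterministically (see source note).
#'
#' @param x numeric item-by-feature matrix with at least 2 rows; all values
#'   finite.
#' @return An object of class `hclust`.
#' @export
wardLinkage <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) .stopf("need at least 2 items to cluster")
  if (any(!is.finite(x))) .stopf("non-finite values in clustering input")
  D2 <- as.matrix(stats::dist(x))^2
  .wardFromD2(D2, sizes = rep(1, nrow(x)), labels = rownames(x))
}

#' Ward.D2 hierarchy from a precomputed dissimilarity
#'
#' Treats the supplied dissimilarities as Euclidean-like distances (they are
#' squared for the Lance-Williams update), matching
#' `stats::hclust(as.dist(d), method = "ward.D2")`. Used to derive final
#' consensus labels from `1 - consensusMatrix`.
#'
#' @param d symmetric non-negative dissimilarity matrix.
#' @return An object of class `hclust`.
#' @export
wardLinkageFromDist <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) .stopf("need at least 2 items to cluster")
  if (any(!is.finite(d))) .stopf("non-finite dissimilarities")
  .wardFromD2(d^2, sizes = rep(1, nrow(d)), labels = rownames(d))
}

#' Cluster items with Ward.D2 and cut at k
#'
#' @param x numeric item-by-feature matrix (rows are the items).
#' @param k number of clusters, `2 <= k <= nrow(x)` (with `k = nrow(x)`
#'   every item is its own cluster).
#' @return Named integer vector of cluster labels, numbered by first
#'   appearance in the input order (as [stats::cutree()]).
#' @examples
#' x <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
#' wardHclust(x, 2)
#' @export
wardHclust <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) .stopf("k = %d exceeds the number of items (%d)", k, n)
  if (k == n)
    return(setNames(seq_len(n), rownames(x)))
  labels <- cutree(wardLinkage(x), k = k)
  if (is.null(names(labels)) && !is.null(rownames(x)))
    names(labels) <- rownames(x)
  labels
}
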