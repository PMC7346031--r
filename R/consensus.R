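# Resampling consensus clustering (Monti-style): repeatedly subsample
# items (and optionally features), cluster each subsample with Ward.D2,
# and record for every item pair the fraction of co-sampled runs in which
# the pair co-clustered. Final labels come from a Ward.D2 cut of
# 1 - consensus, the standard practice when the consensus matrix itself is
# the similarity of record.

#' Consensus clustering configuration
#'
#' Defaults follow the subtyping protocol: k = 5 clusters, 100 resampling
#' repetitions, 80% item subsampling, all features.
#'
#' @param k number of clusters (>= 2).
#' @param reps number of resampling repetitions (>= 1).
#' @param pItem fraction of items drawn (without replacement) per rep,
#'   in (0, 1].
#' @param pFeature fraction of features drawn per rep, in (0, 1].
#' @param seed integer seed for the resampling stream.
#' @return A list of class `clusterConfig`.
#' @export
clusterConfig <- function(k = 5L, reps = 100L, pItem = 0.8, pFeature = 1,
                          seed = 1L) {
  if (k < 2L) .stopf("k must be >= 2")
  if (reps < 1L) .stopf("reps must be >= 1")
  if (pItem <= 0 || pItem > 1 || pFeature <= 0 || pFeature > 1)
    .stopf("pItem and pFeature must lie in (0, 1]")
  structure(list(k = as.integer(k), reps = as.integer(reps), pItem = pItem,
                 pFeature = pFeature, seed = as.integer(seed)),
            class = "clusterConfig")
}

#' Resampling consensus clustering of matrix rows
#'
#' Rows of `x` are the items (genes for metabolic clustering, samples for
#' signature alignment); columns are the features. Each repetition draws
#' `ceiling(pItem * nrow)` items and `ceiling(pFeature * ncol)` features
#' without replacement and clusters the subsample with [wardHclust()] at
#' `k`. The consensus for a pair is its co-clustering count divided by its
#' co-sampling count; pairs never co-sampled get 0 with a warning. Identical
#' seeds give identical output.
#'
#' @param x numeric item-by-feature matrix; `nrow(x) >= k`, `ncol(x) >= 2`.
#' @param config a [clusterConfig()].
#' @return A [ConsensusResult-class].
#' @examples
#' x <- rbind(matrix(rnorm(40), 10, 4), matrix(rnorm(40, 5), 10, 4))
#' rownames(x) <- paste0("g", 1:20)
#' consensusCluster(x, clusterConfig(k = 2, reps = 20, seed = 7))
#' @export
consensusCluster <- function(x, config = clusterConfig()) {
  stopifnot(inherits(config, "clusterConfig"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("item", seq_len(n))
  if (n < config$k) .stopf("fewer items (%d) than k (%d)", n, config$k)
  if (ncol(x) < 2L) .stopf("need at least 2 features")
  nItem <- ceiling(config$pItem * n)
  if (nItem < config$k)
    .stopf("pItem * items (%d) is below k (%d)", nItem, config$k)
  nFeat <- ceiling(config$pFeature * ncol(x))

  set.seed(config$seed)
  coCluster <- matrix(0, n, n)
  coSample <- matrix(0, n, n)
  for (rep in seq_len(config$reps)) {
    items <- sort(sample.int(n, nItem))
    feats <- if (nFeat < ncol(x)) sort(sample.int(ncol(x), nFeat))
             else seq_len(ncol(x))
    labels <- wardHclust(x[items, feats, drop = FALSE], config$k)
    ind <- outer(labels, labels, "==")
    coCluster[items, items] <- coCluster[items, items] + ind
    coSample[items, items] <- coSample[items, items] + 1
  }
  M <- matrix(0, n, n)
  seen <- coSample > 0
  M[seen] <- coCluster[seen] / coSample[seen]
  offDiagUnseen <- !seen & !diag(TRUE, n)
  if (any(offDiagUnseen))
    .warnf("%d item pair(s) never co-sampled; consensus set to 0",
           sum(offDiagUnseen) / 2)
  diag(M)[diag(coSample) > 0] <- 1
  if (any(diag(coSample) == 0))
    .warnf("item(s) never sampled: %s",
           paste(head(rownames(x)[diag(coSample) == 0], 5), collapse = ", "))
  dimnames(M) <- dimnames(coSample) <- list(rownames(x), rownames(x))

  finalLabels <- cutree(wardLinkageFromDist(1 - M), k = config$k)
  names(finalLabels) <- rownames(x)
  new("ConsensusResult", itemIds = rownames(x), consensusMatrix = M,
      samplingCounts = coSample, labels = as.integer(finalLabels) |>
        setNames(rownames(x)),
      k = config$k, config = unclass(config))
}
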