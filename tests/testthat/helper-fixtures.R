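# Shared fixtures for the test suite.

# Small standardized matrix with gene/sample names.
makeStdMatrix <- function(nGenes, nSamples, seed = 1, genes = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples)
  rownames(v) <- genes %||% sprintf("G%03d", seq_len(nGenes))
  colnames(v) <- sprintf("S%03d", seq_len(nSamples))
  ExpressionMatrix(v, "standardized")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One small simulated cohort, computed once per test run.
.cohortCache <- new.env(parent = emptyenv())
smallCohort <- function() {
  if (is.null(.cohortCache$cohort))
    .cohortCache$cohort <- simulateCohort(simConfig(nSamples = 120, seed = 42))
  .cohortCache$cohort
}

# Dataset with five perfectly separated gene blocks of chosen composition,
# used to pin core-cluster selection boundaries. `glyCounts`/`cholCounts`
# give, per block, how many members are annotated glycolytic/cholesterogenic
# (every gene is annotated in exactly one set). Block means are far apart,
# so any sane clustering recovers the blocks exactly.
makeBlockDataset <- function(glyCounts, cholCounts, nSamples = 6, seed = 1) {
  stopifnot(length(glyCounts) == length(cholCounts))
  set.seed(seed)
  glyGenes <- character(); cholGenes <- character()
  rows <- list()
  for (b in seq_along(glyCounts)) {
    g <- if (glyCounts[b]) sprintf("B%d_GLY%02d", b, seq_len(glyCounts[b]))
         else character()
    c2 <- if (cholCounts[b]) sprintf("B%d_CHOL%02d", b, seq_len(cholCounts[b]))
          else character()
    glyGenes <- c(glyGenes, g); cholGenes <- c(cholGenes, c2)
    ids <- c(g, c2)
    rows[[b]] <- matrix(100 * b + rnorm(length(ids) * nSamples, sd = 0.01),
                        length(ids), nSamples, dimnames = list(ids, NULL))
  }
  v <- do.call(rbind, rows)
  colnames(v) <- sprintf("S%02d", seq_len(nSamples))
  # standardized scale tolerates arbitrary signs/magnitudes
  list(em = ExpressionMatrix(v, "standardized"),
       glyGenes = glyGenes, cholGenes = cholGenes)
}

# Exhaustive Ward oracle: recompute the minimal merge-cost pair directly
# from the raw points at every agglomeration step. Returns per-step minimal
# Delta-WSS and whether a height sequence matches sqrt(2 * DeltaWSS).
wardOracleSteps <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  costs <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf
    bestPair <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE])
        cb <- colMeans(x[b, , drop = FALSE])
        cost <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        if (cost < best) { best <- cost; bestPair <- c(i, j) }
      }
    }
    costs <- c(costs, best)
    clusters[[bestPair[1]]] <- c(clusters[[bestPair[1]]],
                                 clusters[[bestPair[2]]])
    clusters[[bestPair[2]]] <- NULL
  }
  costs
}
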