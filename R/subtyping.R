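# Core-cluster selection and quadrant subtype assignment. A consensus gene
# cluster is "core glycolytic" when > 30% of its annotated members come
# from the glycolysis set and "core cholesterogenic" when > 90% come from
# the cholesterol-biosynthesis set; with several candidates the most
# homogeneous (highest relevant fraction) wins, ties broken by cluster
# size then lowest id. Per-sample scores are medians of the core genes on
# the standardized scale, and the quadrant rule assigns: quiescent
# (gly <= 0, chol <= 0), glycolytic (gly > 0, chol <= 0), cholesterogenic
# (gly <= 0, chol > 0), mixed (both > 0).

#' Summarize consensus gene clusters against the two metabolic gene sets
#'
#' Composition fractions are computed over the members annotated in either
#' gene set, and homogeneity is the larger of the two fractions.
#'
#' @param labels named integer cluster labels per gene (e.g.
#'   `consensusLabels()` of a [ConsensusResult-class]).
#' @param glyGenes,cholGenes the glycolytic and cholesterogenic gene sets.
#' @return data.frame with columns `cluster_id`, `n_members`, `n_annotated`,
#'   `n_gly`, `n_chol`, `frac_gly`, `frac_chol`, `homogeneity`.
#' @export
summarizeGeneClusters <- function(labels, glyGenes, cholGenes) {
  if (is.null(names(labels))) .stopf("cluster labels must be named by gene")
  ids <- sort(unique(labels))
  rows <- lapply(ids, function(cl) {
    members <- names(labels)[labels == cl]
    nGly <- sum(members %in% glyGenes)
    nChol <- sum(members %in% cholGenes)
    nAnn <- sum(members %in% union(glyGenes, cholGenes))
    fGly <- if (nAnn) nGly / nAnn else 0
    fChol <- if (nAnn) nChol / nAnn else 0
    data.frame(cluster_id = cl, n_members = length(members),
               n_annotated = nAnn, n_gly = nGly, n_chol = nChol,
               frac_gly = fGly, frac_chol = fChol,
               homogeneity = max(fGly, fChol))
  })
  do.call(rbind, rows)
}

.pickCore <- function(summary, frac, threshold, what) {
  cand <- summary[summary[[frac]] > threshold, , drop = FALSE]
  if (!nrow(cand))
    .stopf("no %s core cluster: no cluster has %s > %g", what, frac, threshold)
  cand <- cand[order(-cand[[frac]], -cand$n_members, cand$cluster_id), ,
               drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Select the core glycolytic and cholesterogenic clusters
#'
#' @param summary cluster summary from [summarizeGeneClusters()].
#' @param labels the named gene cluster labels the summary was built from.
#' @param glyThreshold exclusive glycolytic-fraction cut (default 0.30).
#' @param cholThreshold exclusive cholesterogenic-fraction cut (default
#'   0.90).
#' @return List with elements `glycolytic` and `cholesterogenic`, each a
#'   list holding `cluster_id`, `genes` and `homogeneity`. Fails with an
#'   error naming the category when no cluster qualifies.
#' @export
selectCoreClusters <- function(summary, labels, glyThreshold = 0.30,
                               cholThreshold = 0.90) {
  gly <- .pickCore(summary, "frac_gly", glyThreshold, "glycolytic")
  chol <- .pickCore(summary, "frac_chol", cholThreshold, "cholesterogenic")
  extract <- function(row, frac) list(
    cluster_id = row$cluster_id,
    genes = names(labels)[labels == row$cluster_id],
    fraction = row[[frac]], homogeneity = row$homogeneity)
  list(glycolytic = extract(gly, "frac_gly"),
       cholesterogenic = extract(chol, "frac_chol"))
}

#' Per-sample metabolic scores
#'
#' Medians over the core glycolytic and core cholesterogenic genes on the
#' standardized scale (even counts: mean of the two middle values, the
#' usual median convention). At least 50% of each core set must be present
#' in the matrix.
#'
#' @param em a standardized [ExpressionMatrix-class].
#' @param coreGly,coreChol character vectors of core gene identifiers (or
#'   the list elements returned by [selectCoreClusters()]).
#' @return data.frame with columns `sample_id`, `gly_score`, `chol_score`.
#' @export
computeMetabolicScores <- function(em, coreGly, coreChol) {
  if (is.list(coreGly)) coreGly <- coreGly$genes
  if (is.list(coreChol)) coreChol <- coreChol$genes
  v <- exprValues(em)
  score <- function(genes, what) {
    present <- intersect(genes, rownames(v))
    if (length(present) < length(genes) / 2)
      .stopf("fewer than 50%% of core %s genes present in the matrix (%d/%d)",
             what, length(present), length(genes))
    apply(v[present, , drop = FALSE], 2, median)
  }
  data.frame(sample_id = colnames(v),
             gly_score = unname(score(coreGly, "glycolytic")),
             chol_score = unname(score(coreChol, "cholesterogenic")),
             stringsAsFactors = FALSE)
}

#' Quadrant subtype assignment
#'
#' Applies the quadrant rule to per-sample score pairs, with `<= 0` on the
#' low side of both axes. Every sample receives exactly one of the four
#' labels, so the subtype counts always partition the cohort.
#'
#' @param scores data.frame from [computeMetabolicScores()], or a numeric
#'   vector of glycolytic scores (then `cholScore` must be given).
#' @param cholScore numeric cholesterogenic scores when `scores` is a
#'   vector.
#' @return If given a data.frame, the same data.frame with a `subtype`
#'   factor column; otherwise a factor of subtype labels.
#' @examples
#' assignSubtypes(c(0, 0.5, -0.1, 0.1), c(0, -0.2, 0.3, 0.2))
#' @export
assignSubtypes <- function(scores, cholScore = NULL) {
  if (is.data.frame(scores)) {
    g <- scores$gly_score; c2 <- scores$chol_score
  } else { g <- scores; c2 <- cholScore }
  if (any(!is.finite(g)) || any(!is.finite(c2)))
    .stopf("metabolic scores must be finite")
  lab <- ifelse(g <= 0,
                ifelse(c2 <= 0, "quiescent", "cholesterogenic"),
                ifelse(c2 <= 0, "glycolytic", "mixed"))
  lab <- factor(lab, levels = .SUBTYPES)
  if (is.data.frame(scores)) { scores$subtype <- lab; scores } else lab
}

#' Cluster, select cores, score and assign in one call
#'
#' The canonical subtyping chain on one standardized matrix: consensus
#' clustering of the metabolic genes, core-cluster selection, median
#' scoring and quadrant assignment.
#'
#' @param em standardized [ExpressionMatrix-class].
#' @param glyGenes,cholGenes the metabolic gene sets.
#' @param config a [clusterConfig()].
#' @return List with `consensus` ([ConsensusResult-class]),
#'   `clusterSummary`, `cores` and `subtypes` (score frame with `subtype`
#'   column).
#' @export
classifySamples <- function(em, glyGenes, cholGenes,
                            config = clusterConfig()) {
  genes <- intersect(union(glyGenes, cholGenes), geneIds(em))
  if (length(genes) < config$k)
    .stopf("fewer metabolic genes in the matrix (%d) than k", length(genes))
  cons <- consensusCluster(exprValues(em)[genes, , drop = FALSE], config)
  summary <- summarizeGeneClusters(consensusLabels(cons), glyGenes, cholGenes)
  cores <- selectCoreClusters(summary, consensusLabels(cons))
  scores <- computeMetabolicScores(em, cores$glycolytic, cores$cholesterogenic)
  list(consensus = cons, clusterSummary = summary, cores = cores,
       subtypes = assignSubtypes(scores))
}

#' Multi-dataset subtyping with the homogeneity screen
#'
#' Runs the subtyping chain over a named collection of datasets, skipping
#' (and reporting, never raising) datasets that fail the entry conditions:
#' fewer than `minSamples` samples, no qualifying core cluster, or best
#' core clusters below the homogeneity floor (inclusive: exactly
#' `minHomogeneity` is retained).
#'
#' @param datasets named list; each element a list with components `em`
#'   (standardized [ExpressionMatrix-class]), `glyGenes`, `cholGenes`.
#' @param config a [clusterConfig()].
#' @param minSamples screening floor on the sample count (default 100).
#' @param minHomogeneity inclusive core-cluster homogeneity floor (default
#'   0.75).
#' @return List with `subtypes` (named list of score frames for retained
#'   datasets) and `omitted` (data.frame `dataset`, `reason`).
#' @export
runPanCancer <- function(datasets, config = clusterConfig(),
                         minSamples = 100L, minHomogeneity = 0.75) {
  results <- list()
  omitted <- list()
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    n <- ncol(exprValues(d$em))
    if (n < minSamples) {
      omitted[[nm]] <- sprintf("only %d samples (< %d)", n, minSamples)
      next
    }
    res <- tryCatch(classifySamples(d$em, d$glyGenes, d$cholGenes, config),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) { omitted[[nm]] <- res; next }
    hGly <- res$cores$glycolytic$homogeneity
    hChol <- res$cores$cholesterogenic$homogeneity
    if (hGly < minHomogeneity || hChol < minHomogeneity) {
      omitted[[nm]] <- sprintf(
        "core cluster homogeneity below %.2f (glycolytic %.2f, cholesterogenic %.2f)",
        minHomogeneity, hGly, hChol)
      next
    }
    results[[nm]] <- res$subtypes
  }
  list(subtypes = results,
       omitted = data.frame(dataset = names(omitted),
                            reason = unlist(omitted, use.names = FALSE),
                            stringsAsFactors = FALSE))
}
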