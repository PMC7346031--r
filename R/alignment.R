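# Alignment of samples against published signature-based subtype schemes
# (e.g. the 186-, 17- and 14-gene liver tumor classifiers). A scheme is a
# set of classes, each with direction-weighted signature genes (+1 up, -1
# down). Samples are consensus-clustered on the signature genes and each
# cluster is labeled by the class whose direction-weighted mean score is
# highest in the cluster - a deterministic substitute for the manual
# "semi-automatic" assignment step, stated as such.

#' Construct a signature scheme
#'
#' @param name scheme name.
#' @param signatures named list (one element per class), each a data.frame
#'   or list with `gene` and `direction` (+1 for genes up in the class, -1
#'   for down).
#' @return An object of class `signatureScheme` with elements `name`,
#'   `classes` and `genes` (data.frame `gene_id`, `class`, `direction`).
#' @export
signatureScheme <- function(name, signatures) {
  if (length(signatures) < 2L) .stopf("a scheme needs at least 2 classes")
  rows <- lapply(names(signatures), function(cl) {
    s <- as.data.frame(signatures[[cl]])
    if (!all(c("gene", "direction") %in% names(s)))
      .stopf("class '%s' needs 'gene' and 'direction'", cl)
    if (!all(s$direction %in% c(-1, 1)))
      .stopf("directions must be +1 or -1")
    if (anyDuplicated(s$gene)) .stopf("duplicate gene in class '%s'", cl)
    data.frame(gene_id = as.character(s$gene), class = cl,
               direction = s$direction, stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  if (!nrow(genes)) .stopf("a scheme needs at least 1 gene")
  structure(list(name = name, classes = names(signatures), genes = genes),
            class = "signatureScheme")
}

#' Build a signature scheme from direction-suffixed GMT sets
#'
#' Interprets set names of the form `CLASS_UP` / `CLASS_DOWN` (case
#' insensitive suffix) as the up- and down-regulated signature genes of
#' each class.
#'
#' @param sets named list from [readGmt()].
#' @param name scheme name.
#' @return A `signatureScheme`.
#' @export
schemeFromGmt <- function(sets, name = "scheme") {
  suffix <- toupper(sub(".*_", "", names(sets)))
  cls <- sub("_[^_]*$", "", names(sets))
  if (!all(suffix %in% c("UP", "DOWN")))
    .stopf("set names must end in _UP or _DOWN")
  sigs <- lapply(setNames(unique(cls), unique(cls)), function(cl) {
    up <- unlist(sets[cls == cl & suffix == "UP"], use.names = FALSE)
    down <- unlist(sets[cls == cl & suffix == "DOWN"], use.names = FALSE)
    data.frame(gene = c(up, down),
               direction = rep(c(1, -1), c(length(up), length(down))))
  })
  signatureScheme(name, sigs)
}

#' Assign samples to a published scheme's classes
#'
#' Samples are consensus-clustered (items = samples, features = the
#' scheme's signature genes present in the matrix) into as many clusters
#' as the scheme has classes; each cluster is then labeled by the class
#' with the highest mean direction-weighted signature score among the
#' cluster's samples. Requires at least 50% of the signature genes.
#'
#' @param em standardized [ExpressionMatrix-class].
#' @param scheme a [signatureScheme()].
#' @param config a [clusterConfig()]; its `k` is overridden by the number
#'   of scheme classes.
#' @return Named character vector: scheme class per sample.
#' @export
assignSchemeLabels <- function(em, scheme, config = clusterConfig()) {
  stopifnot(inherits(scheme, "signatureScheme"))
  v <- exprValues(em)
  sig <- scheme$genes[scheme$genes$gene_id %in% rownames(v), , drop = FALSE]
  if (nrow(sig) < nrow(scheme$genes) / 2)
    .stopf("fewer than 50%% of signature genes present; missing: %s",
           paste(head(setdiff(scheme$genes$gene_id, rownames(v)), 10),
                 collapse = ", "))
  config$k <- length(scheme$classes)
  cons <- consensusCluster(t(v[unique(sig$gene_id), , drop = FALSE]), config)
  clusters <- consensusLabels(cons)

  classScore <- vapply(scheme$classes, function(cl) {
    s <- sig[sig$class == cl, , drop = FALSE]
    if (!nrow(s)) return(rep(NA_real_, ncol(v)))
    colMeans(v[s$gene_id, , drop = FALSE] * s$direction)
  }, numeric(ncol(v)))

  labels <- setNames(rep(NA_character_, ncol(v)), colnames(v))
  for (cl in sort(unique(clusters))) {
    inCl <- names(clusters)[clusters == cl]
    means <- colMeans(classScore[inCl, , drop = FALSE])
    best <- which(means == max(means, na.rm = TRUE))
    if (length(best) > 1L)
      .warnf("tied class scores in cluster %d; first class in order wins", cl)
    labels[inCl] <- scheme$classes[best[1]]
  }
  labels
}

#' Cross-tabulate scheme classes against metabolic subtypes
#'
#' Builds the k x 4 contingency table and tests, for every scheme class
#' and every pair of metabolic subtypes, the 2x2 collapse (class vs rest)
#' x (subtype A vs subtype B) with the Fisher exact test, BH-adjusted
#' across all pairs.
#'
#' @param schemeLabels named scheme class per sample.
#' @param metabolicLabels named metabolic subtype per sample (same
#'   samples).
#' @return List with `table` (contingency), `proportions` (class
#'   proportions within each subtype) and `tests` (data.frame with raw and
#'   adjusted p per class/subtype pair).
#' @export
crosstabVsMetabolic <- function(schemeLabels, metabolicLabels) {
  if (!setequal(names(schemeLabels), names(metabolicLabels)))
    .stopf("scheme and metabolic labels cover different samples")
  metabolicLabels <- metabolicLabels[names(schemeLabels)]
  tab <- table(scheme = schemeLabels,
               subtype = factor(as.character(metabolicLabels),
                                levels = .SUBTYPES))
  pairs <- combn(colnames(tab), 2)
  rows <- list()
  for (cl in rownames(tab)) {
    for (j in seq_len(ncol(pairs))) {
      s1 <- pairs[1, j]; s2 <- pairs[2, j]
      m <- matrix(c(tab[cl, s1], sum(tab[, s1]) - tab[cl, s1],
                    tab[cl, s2], sum(tab[, s2]) - tab[cl, s2]),
                  2, 2, byrow = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, subtype_a = s1, subtype_b = s2,
        prop_a = if (sum(tab[, s1])) tab[cl, s1] / sum(tab[, s1]) else NA,
        prop_b = if (sum(tab[, s2])) tab[cl, s2] / sum(tab[, s2]) else NA,
        p_value = fisherExact2x2(m)$p.value, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_adjusted <- bhAdjust(tests$p_value)
  props <- sweep(tab, 2, pmax(colSums(tab), 1), "/")
  list(table = tab, proportions = props, tests = tests)
}

#' Correlate a signature's median expression with the metabolic scores
#'
#' Per sample, the median expression of the signature genes is correlated
#' (Pearson by default, Spearman optionally) with the glycolytic and
#' cholesterogenic scores.
#'
#' @param em standardized [ExpressionMatrix-class].
#' @param scores score frame from [computeMetabolicScores()].
#' @param signatureGenes character vector (>= 3 present genes required).
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame with one row per score axis: `score`, `r`, `p_value`,
#'   `n_genes`.
#' @export
signatureScoreCorrelation <- function(em, scores, signatureGenes,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- exprValues(em)
  present <- intersect(signatureGenes, rownames(v))
  if (length(present) < 3L)
    .stopf("fewer than 3 signature genes present (%d)", length(present))
  sigScore <- apply(v[present, scores$sample_id, drop = FALSE], 2, median)
  testFun <- if (method == "pearson") pearsonTest else spearmanTest
  rows <- lapply(c(gly = "gly_score", chol = "chol_score"), function(col) {
    ht <- testFun(sigScore, scores[[col]])
    data.frame(score = col, r = unname(ht$estimate), p_value = ht$p.value,
               n_genes = length(present), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
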