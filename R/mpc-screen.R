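# Transcriptome-wide anchor-gene correlation screen: Spearman correlation
# of every gene with each of the two mitochondrial pyruvate carrier
# subunits, BH adjustment within each anchor's family, and a joint
# classification of genes concordantly associated with both anchors.

#' Anchor-gene Spearman correlation screen
#'
#' Correlates every gene (excluding the anchors themselves) with the two
#' anchor genes using Spearman's rho on mid-ranks, BH-adjusts the p-values
#' within each anchor's family, and classifies genes: `pos_both` when both
#' correlations are positive with both adjusted p below `alpha`, `neg_both`
#' symmetrically, otherwise `neither`. P-values use the t approximation
#' (the screen requires `n >= 10` samples).
#'
#' @param em an [ExpressionMatrix-class].
#' @param anchor1,anchor2 anchor gene identifiers (default MPC1/MPC2).
#' @param alpha adjusted-p cut for the joint classification (default 0.01).
#' @return data.frame with columns `gene_id`, `rho_1`, `p_1`, `p_adj_1`,
#'   `rho_2`, `p_2`, `p_adj_2`, `class`.
#' @export
mpcCorrelationScreen <- function(em, anchor1 = "MPC1", anchor2 = "MPC2",
                                 alpha = 0.01) {
  v <- exprValues(em)
  missing <- setdiff(c(anchor1, anchor2), rownames(v))
  if (length(missing))
    .stopf("anchor gene(s) absent from the matrix: %s",
           paste(missing, collapse = ", "))
  n <- ncol(v)
  if (n < 10L) .stopf("the correlation screen requires at least 10 samples")
  genes <- setdiff(rownames(v), c(anchor1, anchor2))
  R <- t(apply(v[genes, , drop = FALSE], 1, rank))
  Z <- R - rowMeans(R)
  sz <- sqrt(rowSums(Z^2))
  anchorCor <- function(anchor) {
    ra <- rank(v[anchor, ])
    za <- ra - mean(ra)
    sa <- sqrt(sum(za^2))
    rho <- as.vector(Z %*% za) / (sz * sa)
    rho[sz == 0] <- NA
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    list(rho = rho, p = pmin(p, 1))
  }
  c1 <- anchorCor(anchor1)
  c2 <- anchorCor(anchor2)
  out <- data.frame(gene_id = genes, rho_1 = c1$rho, p_1 = c1$p,
                    p_adj_1 = bhAdjust(c1$p), rho_2 = c2$rho, p_2 = c2$p,
                    p_adj_2 = bhAdjust(c2$p), stringsAsFactors = FALSE)
  sig <- !is.na(out$p_adj_1) & !is.na(out$p_adj_2) &
    out$p_adj_1 < alpha & out$p_adj_2 < alpha
  out$class <- "neither"
  out$class[sig & out$rho_1 > 0 & out$rho_2 > 0] <- "pos_both"
  out$class[sig & out$rho_1 < 0 & out$rho_2 < 0] <- "neg_both"
  rownames(out) <- NULL
  out
}
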