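# Synthetic two-cohort tumor transcriptome generator. Emulates the
# statistical structure the subtyping analysis assumes: block co-expressed
# glycolytic (29) and cholesterogenic (72) gene sets, four planted metabolic
# phenotypes at liver-cohort-like mixing proportions, subtype-linked
# exponential survival hazards, subtype-enriched MYC amplification and TP53
# deletion, subtype-patterned MPC1/MPC2 expression, per-cohort batch
# effects, and a purity distribution whose lower tail exercises the <30%
# exclusion filter. All gene coordinates are a synthetic layout.

# default mixing proportions from the liver-cohort counts 332/164/65/49
# of 610 (quiescent/cholesterogenic/glycolytic/mixed), which sum to 1
# exactly, unlike their rounded percentages
.DEFAULT_PROPS <- c(quiescent = 332, cholesterogenic = 164,
                    glycolytic = 65, mixed = 49) / 610

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 29
#' glycolytic and 72 cholesterogenic genes, four planted phenotypes at
#' proportions 54.4/26.9/11/8%, a cholesterogenic-worst / glycolytic-best
#' hazard ordering, two cohorts with gene-level batch offsets, and a
#' Beta(4, 2) purity distribution putting roughly 3% of samples below the
#' 0.30 purity filter.
#'
#' @param nSamples number of tumor samples.
#' @param nGlyGenes,nCholGenes,nBackgroundGenes gene counts for the
#'   glycolytic block, cholesterogenic block and unstructured background
#'   (the background includes the named genes MYC, TP53, MPC1 and MPC2, so
#'   it must be at least 4).
#' @param subtypeProportions named 4-vector of planted phenotype mixing
#'   proportions; must sum to 1.
#' @param effectSizeDelta standardized mean shift (in units of the per-gene
#'   within-phenotype SD) applied to a block in the samples where it is
#'   active: the glycolytic block in glycolytic and mixed samples, the
#'   cholesterogenic block in cholesterogenic and mixed samples.
#' @param blockCorrelation equicorrelation of the within-phenotype residual
#'   noise among genes of one block, in `[0, 1)`.
#' @param cohortOffsets named per-cohort mean batch shift (log10 scale); the
#'   realized batch effect is gene-specific, N(offset, 0.15).
#' @param cohortProportions sampling probabilities of the cohorts.
#' @param hazardRatios named per-subtype multiplicative hazards (all > 0);
#'   default: glycolytic 1.0 (reference), quiescent 1.5, mixed 1.6,
#'   cholesterogenic 2.0.
#' @param baselineMedianMonths median overall survival of the reference
#'   (glycolytic) phenotype, months.
#' @param censoringRate target fraction of censored samples in `[0, 1)`,
#'   achieved with uniform independent censoring.
#' @param purityShape length-2 Beta shape for tumor purity.
#' @param cnvEnrichment list with per-subtype probabilities `MYC_AMP` and
#'   `TP53_DEL` of planting an amplification over MYC / deletion over TP53.
#' @param mutationRates named per-gene SNV probabilities (subtype-independent).
#' @param indelRate per-gene INDEL probability for the same panel.
#' @param geneNoiseSd per-gene within-phenotype SD on the log10 scale.
#' @param seed master seed; component streams (labels/clinical, copy number,
#'   expression, survival, mutations) derive child seeds from it.
#' @return A validated list of class `simConfig`.
#' @export
simConfig <- function(nSamples = 600L, nGlyGenes = 29L, nCholGenes = 72L,
                      nBackgroundGenes = 200L,
                      subtypeProportions = .DEFAULT_PROPS,
                      effectSizeDelta = 2, blockCorrelation = 0.5,
                      cohortOffsets = c(TCGA = 0, ICGC = 0.6),
                      cohortProportions = c(TCGA = 0.64, ICGC = 0.36),
                      hazardRatios = c(quiescent = 1.5, glycolytic = 1.0,
                                       cholesterogenic = 2.0, mixed = 1.6),
                      baselineMedianMonths = 36, censoringRate = 0.3,
                      purityShape = c(4, 2),
                      cnvEnrichment = list(
                        MYC_AMP = c(quiescent = 0.10, glycolytic = 0.10,
                                    cholesterogenic = 0.45, mixed = 0.30),
                        TP53_DEL = c(quiescent = 0.15, glycolytic = 0.15,
                                     cholesterogenic = 0.45, mixed = 0.30)),
                      mutationRates = c(TP53 = 0.25, CTNNB1 = 0.25,
                                        TTN = 0.20, ALB = 0.10, MUC16 = 0.10),
                      indelRate = 0.05, geneNoiseSd = 0.4, seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples),
              nGlyGenes = as.integer(nGlyGenes),
              nCholGenes = as.integer(nCholGenes),
              nBackgroundGenes = as.integer(nBackgroundGenes),
              subtypeProportions = subtypeProportions,
              effectSizeDelta = effectSizeDelta,
              blockCorrelation = blockCorrelation,
              cohortOffsets = cohortOffsets,
              cohortProportions = cohortProportions,
              hazardRatios = hazardRatios,
              baselineMedianMonths = baselineMedianMonths,
              censoringRate = censoringRate, purityShape = purityShape,
              cnvEnrichment = cnvEnrichment, mutationRates = mutationRates,
              indelRate = indelRate, geneNoiseSd = geneNoiseSd,
              seed = as.integer(seed))
  .validateSimConfig(cfg)
  class(cfg) <- "simConfig"
  cfg
}

.validateSimConfig <- function(cfg) {
  with(cfg, {
    if (nSamples < 1L || nGlyGenes < 1L || nCholGenes < 1L ||
        nBackgroundGenes < 4L)
      .stopf("dimensions must be positive (and >= 4 background genes)")
    p <- subtypeProportions
    if (length(p) != 4L || !setequal(names(p), .SUBTYPES))
      .stopf("subtypeProportions must be named with the four subtypes")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      .stopf("subtypeProportions must be non-negative and sum to 1")
    if (effectSizeDelta < 0) .stopf("effectSizeDelta must be >= 0")
    if (blockCorrelation < 0 || blockCorrelation >= 1)
      .stopf("blockCorrelation must lie in [0, 1)")
    if (!setequal(names(hazardRatios), .SUBTYPES) || any(hazardRatios <= 0))
      .stopf("hazardRatios must be positive and named with the four subtypes")
    if (censoringRate < 0 || censoringRate >= 1)
      .stopf("censoringRate must lie in [0, 1)")
    if (!setequal(names(cohortOffsets), names(cohortProportions)))
      .stopf("cohortOffsets and cohortProportions must share cohort names")
  })
  invisible(cfg)
}

# fixed synthetic coordinate layout (half-open, BED convention)
.geneLayout <- function(glyGenes, cholGenes, bgGenes) {
  special <- data.frame(
    gene_id = c("MYC", "TP53", "MPC1", "MPC2"),
    chrom = c("chr8", "chr17", "chr6", "chr1"),
    start = c(128747680L, 7565097L, 166778407L, 208043546L),
    end = c(128753674L, 7590856L, 166796486L, 208063385L),
    stringsAsFactors = FALSE)
  lay <- function(genes, chrom, origin) {
    n <- length(genes)
    data.frame(gene_id = genes, chrom = chrom,
               start = origin + (seq_len(n) - 1L) * 100000L,
               end = origin + (seq_len(n) - 1L) * 100000L + 10000L,
               stringsAsFactors = FALSE)
  }
  rbind(lay(glyGenes, "chr2", 1000000L), lay(cholGenes, "chr3", 1000000L),
        special, lay(setdiff(bgGenes, special$gene_id), "chr1", 1000000L))
}

# uniform censoring horizon matching the target overall censoring fraction
.censorHorizon <- function(rates, props, target) {
  f <- function(u) sum(props * (1 - exp(-rates * u)) / (rates * u)) - target
  uniroot(f, c(1e-3, 1e6))$root
}

#' Generate a synthetic tumor cohort
#'
#' Draws planted subtype labels, block-structured log-scale expression
#' converted to per-sample TPM, per-subtype exponential survival with
#' uniform censoring, copy-number segments with subtype-enriched MYC
#' amplification and TP53 deletion plus neutral passenger segments, and a
#' subtype-independent SNV/INDEL table. Identical configuration and seed
#' give byte-identical output.
#'
#' @param config a [simConfig()] object.
#' @return A [SyntheticCohort-class].
#' @examples
#' cohort <- simulateCohort(simConfig(nSamples = 40, nBackgroundGenes = 10))
#' cohort
#' @export
simulateCohort <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  .validateSimConfig(config)
  seeds <- .childSeeds(config$seed, 5L)
  n <- config$nSamples
  sampleIds <- sprintf("S%04d", seq_len(n))

  ## stream 1: labels, cohorts, purity, metastasis
  set.seed(seeds[1])
  props <- config$subtypeProportions[.SUBTYPES]
  labels <- sample(.SUBTYPES, n, replace = TRUE, prob = props)
  cohorts <- sample(names(config$cohortOffsets), n, replace = TRUE,
                    prob = config$cohortProportions[names(config$cohortOffsets)])
  purity <- rbeta(n, config$purityShape[1], config$purityShape[2])
  metastatic <- rbinom(n, 1L, 0.3)

  ## stream 2: copy number (flags feed expression coupling)
  set.seed(seeds[2])
  pAmp <- config$cnvEnrichment$MYC_AMP[labels]
  pDel <- config$cnvEnrichment$TP53_DEL[labels]
  mycAmp <- rbinom(n, 1L, pAmp) == 1L
  tp53Del <- rbinom(n, 1L, pDel) == 1L
  segs <- list()
  if (any(mycAmp)) {
    idx <- which(mycAmp)
    segs$amp <- data.frame(
      sample_id = sampleIds[idx], chrom = "chr8",
      start = 128747681L - as.integer(runif(length(idx), 0, 2e5)),
      end = 128753674L + as.integer(runif(length(idx), 0, 2e5)),
      n_probes = sample(20:100, length(idx), replace = TRUE),
      seg_mean = runif(length(idx), 0.3, 0.9),
      copy_status = sample(3:5, length(idx), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  if (any(tp53Del)) {
    idx <- which(tp53Del)
    segs$del <- data.frame(
      sample_id = sampleIds[idx], chrom = "chr17",
      start = 7565098L - as.integer(runif(length(idx), 0, 2e5)),
      end = 7590856L + as.integer(runif(length(idx), 0, 2e5)),
      n_probes = sample(20:100, length(idx), replace = TRUE),
      seg_mean = -runif(length(idx), 0.3, 0.9),
      copy_status = sample(0:1, length(idx), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  nPass <- stats::rpois(n, 2)
  if (sum(nPass) > 0) {
    who <- rep(seq_len(n), nPass)
    st <- as.integer(runif(length(who), 1e6, 1e8))
    segs$passenger <- data.frame(
      sample_id = sampleIds[who],
      chrom = paste0("chr", sample(1:22, length(who), replace = TRUE)),
      start = st, end = st + as.integer(runif(length(who), 1e4, 1e6)),
      n_probes = sample(5:60, length(who), replace = TRUE),
      seg_mean = rnorm(length(who), 0, 0.15),
      copy_status = 2L, stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, unname(segs))
  if (is.null(segments))
    segments <- data.frame(sample_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           n_probes = integer(), seg_mean = numeric(),
                           copy_status = integer())
  segments <- segments[order(segments$sample_id, segments$chrom,
                             segments$start), , drop = FALSE]
  rownames(segments) <- NULL

  ## stream 3: expression
  set.seed(seeds[3])
  glyGenes <- sprintf("GLY%02d", seq_len(config$nGlyGenes))
  cholGenes <- sprintf("CHOL%02d", seq_len(config$nCholGenes))
  bgGenes <- c("MYC", "TP53", "MPC1", "MPC2",
               sprintf("BG%04d", seq_len(config$nBackgroundGenes - 4L)))
  genes <- c(glyGenes, cholGenes, bgGenes)
  sigma <- config$geneNoiseSd
  rho <- config$blockCorrelation
  delta <- config$effectSizeDelta

  baseline <- c(rep(1.5, length(glyGenes) + length(cholGenes)),
                runif(length(bgGenes), 1, 3))
  batch <- vapply(names(config$cohortOffsets), function(co)
    rnorm(length(genes), config$cohortOffsets[[co]], 0.15),
    numeric(length(genes)))
  rownames(batch) <- genes

  blockNoise <- function(nGenes) {
    shared <- rnorm(n)
    sqrt(rho) * matrix(shared, nGenes, n, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(nGenes * n), nGenes, n)
  }
  glyActive <- labels %in% c("glycolytic", "mixed")
  cholActive <- labels %in% c("cholesterogenic", "mixed")
  L <- matrix(0, length(genes), n, dimnames = list(genes, sampleIds))
  L[glyGenes, ] <- sigma * blockNoise(length(glyGenes)) +
    sigma * delta * matrix(glyActive, length(glyGenes), n, byrow = TRUE)
  L[cholGenes, ] <- sigma * blockNoise(length(cholGenes)) +
    sigma * delta * matrix(cholActive, length(cholGenes), n, byrow = TRUE)
  L[bgGenes, ] <- sigma * matrix(rnorm(length(bgGenes) * n),
                                 length(bgGenes), n)
  # anchor-gene and driver-gene patterning
  isGly <- labels == "glycolytic"
  isChol <- labels == "cholesterogenic"
  L["MPC1", ] <- L["MPC1", ] + 0.8 * sigma * isGly
  L["MPC2", ] <- L["MPC2", ] - 0.8 * sigma * isGly + 0.4 * sigma * isChol
  L["MYC", ] <- L["MYC", ] + 0.6 * sigma * mycAmp
  L["TP53", ] <- L["TP53", ] - 0.6 * sigma * tp53Del
  L <- L + baseline + batch[, cohorts]
  linear <- 10^L
  tpm <- sweep(linear, 2, colSums(linear), "/") * 1e6
  expression <- ExpressionMatrix(tpm, "tpm")

  ## stream 4: survival
  set.seed(seeds[4])
  lambda0 <- log(2) / config$baselineMedianMonths
  rates <- lambda0 * config$hazardRatios[labels]
  eventTime <- rexp(n, rates)
  if (config$censoringRate > 0) {
    horizon <- .censorHorizon(lambda0 * config$hazardRatios[.SUBTYPES],
                              props, config$censoringRate)
    censTime <- runif(n, 0, horizon)
  } else censTime <- rep(Inf, n)
  osMonths <- pmin(eventTime, censTime)
  event <- as.integer(eventTime <= censTime)

  clinical <- data.frame(sample_id = sampleIds, os_months = osMonths,
                         event = event, cohort = cohorts, purity = purity,
                         metastatic = metastatic, stringsAsFactors = FALSE)

  ## stream 5: mutations (subtype-independent rates)
  set.seed(seeds[5])
  muts <- list()
  for (g in names(config$mutationRates)) {
    hit <- rbinom(n, 1L, config$mutationRates[[g]]) == 1L
    if (any(hit))
      muts[[paste0(g, "_snv")]] <- data.frame(
        gene = g, sample = sampleIds[hit], class = "SNV",
        stringsAsFactors = FALSE)
    hitI <- rbinom(n, 1L, config$indelRate) == 1L
    if (any(hitI))
      muts[[paste0(g, "_indel")]] <- data.frame(
        gene = g, sample = sampleIds[hitI], class = "INDEL",
        stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, unname(muts))
  if (is.null(mutations))
    mutations <- data.frame(gene = character(), sample = character(),
                            class = character())
  rownames(mutations) <- NULL

  new("SyntheticCohort", expression = expression, clinical = clinical,
      segments = segments, mutations = mutations,
      geneIntervals = .geneLayout(glyGenes, cholGenes, bgGenes),
      geneSets = list(glycolytic = glyGenes, cholesterogenic = cholGenes),
      truthLabels = setNames(labels, sampleIds),
      config = unclass(config))
}

#' Write a synthetic cohort to a directory of standard-format files
#'
#' Emits `expression.tsv` (TPM), `clinical.tsv`, `segments.seg`,
#' `gene_sets.gmt`, `genes.bed`, `mutations.tsv` and `truth_labels.tsv`,
#' each readable by the corresponding reader.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             segments = file.path(dir, "segments.seg"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             bed = file.path(dir, "genes.bed"),
             mutations = file.path(dir, "mutations.tsv"),
             truth = file.path(dir, "truth_labels.tsv"))
  writeExpression(cohort@expression, paths["expression"])
  writeClinical(cohort@clinical, paths["clinical"])
  writeSeg(cohort@segments, paths["segments"])
  writeGmt(list(GLYCOLYSIS = cohort@geneSets$glycolytic,
                CHOLESTEROL_BIOSYNTHESIS = cohort@geneSets$cholesterogenic),
           paths["gene_sets"],
           descriptions = c(GLYCOLYSIS = "glycolytic",
                            CHOLESTEROL_BIOSYNTHESIS = "cholesterogenic"))
  writeBed(cohort@geneIntervals, paths["bed"])
  writeMutations(cohort@mutations, paths["mutations"])
  .writeTsv(data.frame(sample_id = names(cohort@truthLabels),
                       subtype = unname(cohort@truthLabels)), paths["truth"])
  invisible(paths)
}
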