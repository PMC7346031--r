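# End-to-end orchestration: read -> preprocess -> cluster -> core-select ->
# score -> assign -> genomics -> survival -> alignment, with per-stage
# error context, per-stage timing, and a machine-readable JSON run summary
# stamped with the seed and a configuration hash. Re-running an identical
# configuration reproduces every output byte-for-byte.

#' Pipeline configuration
#'
#' @param paths named list of input files: `expression`, `clinical`,
#'   `geneSets` (GMT with a glycolytic and a cholesterogenic set),
#'   `segments`, `bed`; optional `mutations`, `signatureGmt`.
#' @param expressionScale scale of the expression file: `"tpm"` (default)
#'   or `"counts"` (then gene lengths are taken from the BED intervals).
#' @param preprocess a [preprocessConfig()].
#' @param cluster a [clusterConfig()].
#' @param cnv a [cnvConfig()].
#' @param alphaEnrichment significance level for enrichment reporting.
#' @param alphaScreen adjusted-p level of the anchor correlation screen.
#' @param minSurvivalMonths exclusive lower survival cut (default 1).
#' @param runScreen run the MPC1/MPC2 correlation screen when both anchors
#'   are present.
#' @param seed master seed; overrides the cluster config seed.
#' @return A list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(paths, expressionScale = c("tpm", "counts"),
                           preprocess = preprocessConfig(),
                           cluster = clusterConfig(), cnv = cnvConfig(),
                           alphaEnrichment = 0.05, alphaScreen = 0.01,
                           minSurvivalMonths = 1, runScreen = TRUE,
                           seed = 1L) {
  need <- c("expression", "clinical", "geneSets", "segments", "bed")
  if (!all(need %in% names(paths)))
    .stopf("paths must include: %s", paste(need, collapse = ", "))
  cluster$seed <- as.integer(seed)
  structure(list(paths = paths,
                 expressionScale = match.arg(expressionScale),
                 preprocess = preprocess, cluster = cluster, cnv = cnv,
                 alphaEnrichment = alphaEnrichment,
                 alphaScreen = alphaScreen,
                 minSurvivalMonths = minSurvivalMonths,
                 runScreen = runScreen, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Leaf values under `preprocess`, `cluster` and `cnv` override the
#' defaults of the corresponding config constructors.
#'
#' @param path YAML file with a `paths` block and optional config blocks.
#' @return A [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(paths = y$paths)
  for (nm in c("expressionScale", "alphaEnrichment", "alphaScreen",
               "minSurvivalMonths", "runScreen", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$preprocess))
    args$preprocess <- do.call(preprocessConfig, y$preprocess)
  if (!is.null(y$cluster)) args$cluster <- do.call(clusterConfig, y$cluster)
  if (!is.null(y$cnv)) args$cnv <- do.call(cnvConfig, y$cnv)
  do.call(pipelineConfig, args)
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  log(sprintf("stage %-12s %6.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full subtyping pipeline
#'
#' @param config a [pipelineConfig()] or path to its YAML file.
#' @param outputDir directory for result tables and the JSON run summary.
#' @param quiet suppress stage logging to stderr.
#' @return Invisibly, a list with the subtype table, cluster summary,
#'   enrichment results, survival tests, alignment (when configured),
#'   screen results (when run), and the run summary.
#' @export
runPipeline <- function(config, outputDir = ".", quiet = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  log <- if (quiet) function(...) invisible() else
    function(msg) message(msg)
  hash <- .configHash(config)
  timings <- list()
  p <- config$paths

  inputs <- .stage("read", log, {
    sets <- readGmt(p$geneSets)
    desc <- attr(sets, "descriptions")
    pickSet <- function(category, pattern) {
      hit <- which(desc == category)
      if (!length(hit)) hit <- grep(pattern, names(sets), ignore.case = TRUE)
      if (!length(hit))
        .stopf("cannot identify the %s gene set in the GMT", category)
      sets[[hit[1]]]
    }
    list(expression = readExpression(p$expression,
                                     scaleTag = config$expressionScale),
         clinical = readClinical(p$clinical),
         glyGenes = pickSet("glycolytic", "^GLY"),
         cholGenes = pickSet("cholesterogenic", "CHOL"),
         segments = readSeg(p$segments), bed = readBed(p$bed),
         mutations = if (!is.null(p$mutations)) readMutations(p$mutations)
                     else NULL)
  })

  pre <- .stage("preprocess", log, {
    em <- inputs$expression
    if (scaleTag(em) == "counts") {
      lengths <- setNames(inputs$bed$end - inputs$bed$start,
                          inputs$bed$gene_id)
      em <- tpmNormalize(em, lengths)
    }
    if (scaleTag(em) == "tpm") em <- logTransform(em)
    flt <- filterByPurity(em, inputs$clinical,
                          config$preprocess$purityThreshold)
    em <- flt$expression
    clinical <- flt$clinical
    if (config$preprocess$batchMethod == "per_cohort_zscore") {
      em <- batchCorrect(em, setNames(clinical$cohort, clinical$sample_id))
    }
    list(expression = em, clinical = clinical, excluded = flt$excluded)
  })

  sub <- .stage("subtype", log,
    classifySamples(pre$expression, inputs$glyGenes, inputs$cholGenes,
                    config$cluster))
  subtypes <- sub$subtypes
  labels <- setNames(as.character(subtypes$subtype), subtypes$sample_id)

  genomics <- .stage("genomics", log, {
    called <- callCnvEvents(inputs$segments, config$cnv)
    cnvEvents <- mapEventsToGenes(called, inputs$bed)
    events <- combineGeneEvents(cnvEvents, inputs$mutations)
    events <- events[events$sample_id %in% names(labels), , drop = FALSE]
    enrichment <- if (nrow(events))
      testEventEnrichment(events, labels) else NULL
    assoc <- list()
    for (spec in list(c("MYC", "AMP"), c("TP53", "DEL"))) {
      a <- tryCatch(scoreGeneAssociation(subtypes, pre$expression, events,
                                         spec[1], spec[2]),
                    error = function(e) NULL)
      if (!is.null(a)) assoc[[paste(spec, collapse = "_")]] <- a
    }
    list(events = events, enrichment = enrichment, association = assoc)
  })

  surv <- .stage("survival", log, {
    cl <- filterMinSurvival(pre$clinical, config$minSurvivalMonths)
    cl$subtype <- labels[cl$sample_id]
    tests <- list(all = logrankTest(cl$os_months, cl$event, cl$subtype))
    cg <- cl[cl$subtype %in% c("cholesterogenic", "glycolytic"), ]
    if (length(unique(cg$subtype)) == 2L && sum(cg$event) > 0)
      tests$chol_vs_gly <- logrankTest(cg$os_months, cg$event, cg$subtype)
    for (m in c(0L, 1L)) {
      sl <- cg[!is.na(cg$metastatic) & cg$metastatic == m, ]
      if (length(unique(sl$subtype)) == 2L && sum(sl$event) > 0)
        tests[[if (m) "chol_vs_gly_metastatic" else
               "chol_vs_gly_nonmetastatic"]] <-
          logrankTest(sl$os_months, sl$event, sl$subtype)
    }
    curves <- lapply(split(cl, cl$subtype), function(d)
      kmEstimate(d$os_months, d$event))
    list(clinical = cl, tests = tests, curves = curves)
  })

  alignment <- NULL
  if (!is.null(p$signatureGmt)) {
    alignment <- .stage("alignment", log, {
      scheme <- schemeFromGmt(readGmt(p$signatureGmt))
      schemeLabels <- assignSchemeLabels(pre$expression, scheme,
                                         config$cluster)
      c(list(labels = schemeLabels),
        crosstabVsMetabolic(schemeLabels, labels))
    })
  }

  screen <- NULL
  if (config$runScreen &&
      all(c("MPC1", "MPC2") %in% geneIds(pre$expression)) &&
      ncol(exprValues(pre$expression)) >= 10L) {
    screen <- .stage("screen", log,
      mpcCorrelationScreen(pre$expression, alpha = config$alphaScreen))
  }

  out <- .stage("write", log, {
    files <- c(subtypes = file.path(outputDir, "subtypes.tsv"),
               clusters = file.path(outputDir, "cluster_summary.tsv"),
               survival = file.path(outputDir, "survival_tests.tsv"))
    .writeTsv(subtypes, files["subtypes"])
    .writeTsv(sub$clusterSummary, files["clusters"])
    survDf <- do.call(rbind, lapply(names(surv$tests), function(nm) {
      ht <- surv$tests[[nm]]
      data.frame(contrast = nm, chisq = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value, n = ht$n)
    }))
    .writeTsv(survDf, files["survival"])
    if (!is.null(genomics$enrichment)) {
      files["enrichment"] <- file.path(outputDir, "enrichment.tsv")
      .writeTsv(genomics$enrichment, files["enrichment"])
    }
    if (nrow(genomics$events)) {
      files["events"] <- file.path(outputDir, "events.tsv")
      .writeTsv(genomics$events, files["events"])
    }
    if (!is.null(alignment)) {
      files["alignment"] <- file.path(outputDir, "alignment_tests.tsv")
      .writeTsv(alignment$tests, files["alignment"])
    }
    if (!is.null(screen)) {
      files["screen"] <- file.path(outputDir, "mpc_screen.tsv")
      .writeTsv(screen, files["screen"])
    }
    files
  })

  summary <- list(
    seed = config$seed, config_hash = hash,
    n_samples_input = length(inputs$clinical$sample_id),
    n_samples_analyzed = nrow(subtypes),
    n_excluded_low_purity = length(pre$excluded),
    subtype_counts = as.list(table(subtypes$subtype)),
    n_events_called = nrow(genomics$events),
    output_hashes = as.list(tools::md5sum(unname(out))),
    outputs = as.list(out))
  summaryPath <- file.path(outputDir, "run_summary.json")
  jsonlite::write_json(summary, summaryPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(subtypes = subtypes, clusterSummary = sub$clusterSummary,
                 cores = sub$cores, consensus = sub$consensus,
                 genomics = genomics, survival = surv,
                 alignment = alignment, screen = screen, summary = summary))
}

#' Plot a consensus matrix
#'
#' Items are ordered by their final cluster labels; darker cells mark pairs
#' that co-cluster across most resampling runs.
#'
#' @param result a [ConsensusResult-class].
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the item ordering used.
#' @export
plotConsensusMatrix <- function(result, ...) {
  ord <- order(consensusLabels(result))
  M <- consensusMatrix(result)[ord, ord]
  graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), M[, rev(seq_len(ncol(M)))],
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  xlab = "", ylab = "", axes = FALSE, ...)
  invisible(ord)
}
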