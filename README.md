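# MetaboSubtype

Glycolytic/cholesterogenic metabolic subtyping of bulk tumor
transcriptomes, with the full analysis protocol — consensus clustering,
quadrant scoring, copy-number association, survival contrasts, signature
alignment — implemented as a single installable R package, plus a fully
specified synthetic cohort generator so every stage can be exercised and
tested without any external downloads.

## The science

Tumors reprogram central carbon metabolism, and two axes of that
reprogramming — glycolysis and cholesterol biosynthesis — stratify
hepatocellular carcinoma cohorts into four phenotypes with distinct
prognoses:

- **quiescent** — low glycolytic, low cholesterogenic expression;
- **glycolytic** — high glycolytic only (best survival in this protocol's
  reference conditions);
- **cholesterogenic** — high cholesterogenic only (worst survival);
- **mixed** — both axes high.

The protocol, end to end:

1. **Normalization.** Counts → TPM → `log10(x + 1)`; samples with tumor
   purity strictly below 30% are excluded; per-cohort gene-wise z-scoring
   removes additive batch offsets and centers every gene
   (`tpmNormalize()`, `logTransform()`, `filterByPurity()`,
   `batchCorrect()`).
2. **Consensus clustering of the metabolic genes.** The 29 glycolysis and
   72 cholesterol-biosynthesis genes are clustered with Monti-style
   resampling consensus (k = 5, 100 repetitions, 80% item subsampling)
   over a from-scratch Ward.D2 linkage whose merge criterion and
   tie-breaking are fully specified (`consensusCluster()`,
   `wardLinkage()`).
3. **Core-cluster selection.** A cluster is *core glycolytic* when more
   than 30% of its annotated members are glycolysis genes and *core
   cholesterogenic* when more than 90% are cholesterol-biosynthesis genes
   (`selectCoreClusters()`).
4. **Quadrant assignment.** Each sample's glycolytic and cholesterogenic
   scores are the medians of the core genes on the standardized scale;
   the sign quadrant of the score pair gives the subtype, with (0, 0)
   assigned to quiescent (`computeMetabolicScores()`,
   `assignSubtypes()`).
5. **Genomic events.** Segmented copy-number calls are thresholded (≥ 10
   probes, |segment mean| > 0.2, integer copy status ≥ 3 / ≤ 1 when
   present), mapped to gene intervals with the SEG-vs-BED coordinate
   conventions handled explicitly, combined with SNV/INDEL records, and
   tested for per-subtype enrichment with an in-package Fisher exact test
   and Benjamini-Hochberg adjustment (`callCnvEvents()`,
   `mapEventsToGenes()`, `testEventEnrichment()`).
6. **Survival.** Kaplan-Meier product-limit curves and the log-rank test
   (hypergeometric variance, k − 1 df) contrast the subtypes, overall and
   within metastasis strata (`kmEstimate()`, `logrankTest()`).
7. **Signature alignment and anchor screen.** Samples are aligned
   against published direction-weighted signature schemes and
   cross-tabulated against the metabolic subtypes; a transcriptome-wide
   Spearman screen finds genes concordantly correlated with the two
   mitochondrial pyruvate carrier subunits MPC1/MPC2
   (`assignSchemeLabels()`, `crosstabVsMetabolic()`,
   `mpcCorrelationScreen()`).

The statistical primitives the analysis depends on — Fisher exact,
Benjamini-Hochberg, Spearman (exact for n ≤ 9), Wilcoxon rank-sum (exact
branch included), hypergeometric enrichment, Kaplan-Meier and the
log-rank test — are implemented in the package and cross-checked in the
test suite against independent reference implementations
(`stats::fisher.test`, `stats::p.adjust`, `survival::survfit`,
`survival::survdiff`, brute-force enumeration).

## Worked example

```r
library(MetaboSubtype)

cohort <- simulateCohort(simConfig(nSamples = 200, seed = 7))
cohort
#> SyntheticCohort: 200 samples, 301 genes, 2 cohorts
#> planted subtypes: quiescent=101, glycolytic=19, cholesterogenic=61, mixed=19
#> segments: 467, mutations: 214

em  <- logTransform(cohortExpression(cohort))
flt <- filterByPurity(em, cohortClinical(cohort), 0.30)
z   <- batchCorrect(flt$expression,
                    setNames(flt$clinical$cohort, flt$clinical$sample_id))
z
#> ExpressionMatrix: 301 genes x 195 samples [scale: standardized]

res <- classifySamples(z, cohort@geneSets$glycolytic,
                       cohort@geneSets$cholesterogenic,
                       clusterConfig(seed = 7))
res$clusterSummary
#>   cluster_id n_members n_annotated n_gly n_chol frac_gly frac_chol homogeneity
#> 1          1        29          29    29      0        1         0           1
#> 2          2        19          19     0     19        0         1           1
#> 3          3        13          13     0     13        0         1           1
#> 4          4        18          18     0     18        0         1           1
#> 5          5        22          22     0     22        0         1           1

table(res$subtypes$subtype)
#>       quiescent      glycolytic cholesterogenic           mixed
#>              60              43              53              39

head(res$subtypes, 3)
#>   sample_id  gly_score chol_score         subtype
#> 1     S0001 -0.9503836 0.59355851 cholesterogenic
#> 2     S0002 -0.3595912 0.08336098 cholesterogenic
#> 3     S0003  0.6788381 0.15905248           mixed

surv <- flt$clinical[flt$clinical$os_months >= 1, ]
surv$subtype <- res$subtypes$subtype[match(surv$sample_id,
                                           res$subtypes$sample_id)]
lr <- logrankTest(surv$os_months, surv$event, surv$subtype)
c(chisq = unname(lr$statistic), df = unname(lr$parameter), p = lr$p.value)
#>    chisq       df        p
#> 1.400549 3.000000 0.705406
```

(With only 200 samples the survival contrast is underpowered; the
full-size default cohort of 600 gives chi-square ≈ 25 on 3 df.)

The whole chain — including copy-number calling, enrichment, survival and
the MPC screen, with every table written to disk plus a JSON run summary
stamped with the seed and a configuration hash — is one call:

```r
paths <- writeCohort(cohort, "cohort_dir")
cfg <- pipelineConfig(paths = list(
  expression = paths[["expression"]], clinical = paths[["clinical"]],
  geneSets = paths[["gene_sets"]],  segments = paths[["segments"]],
  bed = paths[["bed"]],             mutations = paths[["mutations"]]),
  seed = 7)
res <- runPipeline(cfg, "results_dir")
```

A command-line wrapper lives at `inst/scripts/metabosubtype.R`
(`simulate` and `run` subcommands), and `readPipelineConfig()` accepts
the same configuration as YAML.

## The synthetic cohort generator

`simConfig()` / `simulateCohort()` emulate the statistical structure the
protocol assumes: equicorrelated co-expression blocks for the two gene
sets with a standardized activation shift in the phenotypes where a block
is active, four planted phenotypes at liver-cohort-like mixing
proportions, two cohorts with gene-specific batch offsets, a Beta(4, 2)
purity distribution whose lower tail exercises the purity filter,
subtype-linked exponential survival with uniform censoring calibrated to
a target censoring rate, subtype-enriched MYC amplification and TP53
deletion segments coupled to expression, and MPC1/MPC2 anchor patterning.
All randomness flows from one seed through five independent component
streams; identical configurations are byte-identical. See the methods
vignette (`vignettes/metabolic-subtyping-methods.Rmd`) for the model,
every parameter's rationale, and the generator's known limitations —
including why quadrant recovery degrades as the within-block residual
correlation grows.

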