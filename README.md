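# ImmuneSubtypes

Tumors differ widely in how immune cells infiltrate and act inside them, and
in ovarian cancer those differences carry prognostic information that stage
and histology miss. `ImmuneSubtypes` is an R package for deriving **immune
subtypes** from bulk expression of immune-related genes: it discovers
co-expressed **gene modules** (GMs) and sample **subtypes** (ISs) by
bootstrap consensus clustering, transfers the subtypes to new cohorts, and
quantifies their association with survival and treatment response. It is
aimed at computational biologists integrating multi-cohort expression data
(e.g. RNA-seq plus microarray) with clinical follow-up.

## Methods at a glance

- **Integration.** Cohorts are merged on a curated immune gene list
  (`curateGenes()`, `mergeCohorts()`) and cohort batch effects removed with
  parametric empirical-Bayes location/scale adjustment (ComBat;
  `combatAdjust()`), then gene rows are z-scored (`standardizeGenes()`).
- **Consensus clustering** (`consensusCluster()`, `discoverSubtypes()`).
  For b = 1..B resamples, a fraction f of items is drawn and clustered by
  agglomerative hierarchical clustering on Euclidean distance, cut at k.
  The consensus matrix is
  M(i,j) = #{resamples where i,j co-cluster} / #{resamples containing both},
  and the final partition is an average-linkage cut of 1 − M. Cluster count
  selection uses the empirical CDF of consensus values: with A(k) the area
  under that CDF, `selectK()` picks the largest k whose relative gain
  Δ(k) = (A(k) − A(k−1))/A(k−1) exceeds a threshold (default 0.05).
  Defaults follow common practice for this analysis: B = 500, f = 0.8,
  k swept over 2..10.
- **Module activity and transfer.** A module's activity in a sample is the
  mean expression of its genes (`moduleActivity()`). Subtype centroids in
  activity space (`subtypeCentroids()`) let new samples be labelled by
  maximal Pearson correlation (`assignByCentroid()`), or cluster-first and
  match clusters to centroids (`clusterThenMatch()`). The intermediate
  subtype (by convention IS3), which lacks distinguishing module activity,
  is excluded from matching by default and can absorb low-confidence
  samples via an ambiguity threshold.
- **Classification.** A multinomial logistic model on the module activities
  (`fitMultinomial()`; reference-class-zero softmax, small ridge), with
  one-vs-rest AUROC (Mann–Whitney form) and step-interpolated AUPRC
  (`evaluateOvr()`).
- **Outcome statistics.** Kaplan–Meier curves, k-group log-rank tests and
  Cox proportional-hazards fits with explicit categorical baselines
  (`kmEstimate()`, `logrankTest()`, `coxFit()`, `subtypeSurvivalReport()`),
  plus Kruskal–Wallis with Dunn–Bonferroni post hoc, rank-sum,
  Fisher/chi-square, and the derived microenvironment quantities stromal
  fraction (1 − purity) and absolute immune-cell proportions (relative ×
  leukocyte fraction).
- **Synthetic cohorts with ground truth.** `simulationConfig()` /
  `simulateCohort()` generate cohorts with planted modules, five subtype
  signatures (one intermediate), gene-wise batch effects, exponential
  proportional-hazards survival and response labels — the package's
  testbed, with truth accessors (`trueModules()`, `trueSubtypes()`,
  `plantedCentroids()`).

## Worked example

`runPipeline()` chains every stage on synthetic data (two discovery cohorts
with a mild batch offset, one batch-shifted validation cohort) and writes
all intermediate tables plus a reproducibility manifest:

```r
library(ImmuneSubtypes)
mf <- runPipeline(simulationConfig(), outDir = "run1", seed = 1, nBoot = 100)
```

```
[simulate] 3 cohort(s): discoveryA, discoveryB, validation
[preprocess] 500 genes x 900 samples after merge+ComBat
[discover] modules sized 134/125/125/116; subtypes sized 120/120/120/120/120
[transfer] centroid vs cluster-match agreement 91.7%
[classify] macro AUROC 0.998, macro AUPRC 0.994
[survival] overall log-rank p = 2.037e-09
[compare] 4 module-activity tests
```

Reading the output: the 200 planted module genes are recovered inside four
gene clusters (the surplus in each is unstructured noise genes attaching to
the nearest module); all five 120-sample subtypes are recovered exactly;
the two transfer routes agree on 91.7% of validation samples; the
module-activity classifier separates subtypes in the held-out cohort at
macro AUROC 0.998; and the planted subtype-survival contrast (best- vs
worst-prognosis subtype, hazard ratio exp(−0.7) vs exp(+0.3)) yields an
overall log-rank p of 2×10⁻⁹. `run1/manifest.json` records seeds, stage
logs and MD5 checksums of every table; re-running with the same seed
reproduces them byte-identically.

A thin command-line front-end is installed at
`inst/scripts/immusub.R` (`immusub.R run --out DIR --seed N ...`).

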