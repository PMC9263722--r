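---
title: "Immune subtyping by consensus clustering: models, parameters and design"
author: "ImmuneSubtypes package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune subtyping methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
the methodology left room. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The analysis model

The package treats bulk, log-scale expression of a curated immune gene set
as a mixture of a small number of co-expressed **gene modules** (immune
programs) whose per-sample mean expression — the **module activity** — is a
low-dimensional, platform-portable summary of a tumor's immune state.
Samples sharing an activity profile form an **immune subtype**. Three
modelling assumptions follow:

1. *Module structure is a hard partition.* Every clustered gene belongs to
   at most one module; activity is an unweighted arithmetic mean. This is
   deliberately simple: means of tens of z-scored genes are robust to
   single-gene noise and transfer across platforms without re-weighting.
2. *Subtypes are discrete.* Consensus clustering yields a hard sample
   partition; one subtype may genuinely be "intermediate" (see the transfer
   section) and is handled specially rather than forced.
3. *Survival follows proportional hazards by subtype.* Subtype enters a
   Cox model as a categorical covariate with an explicitly declared
   baseline level.

## Consensus clustering

`consensusCluster()` re-implements Monti-style consensus clustering from
first principles, because the consensus matrix itself (not just the final
partition) is the evidence object the analysis interprets.

* Inner clusterer: agglomerative hierarchical clustering on **Euclidean**
  distance. Linkage is selectable (`average`, `complete`, `ward`); the
  default is **average**, the common inner default for this procedure,
  since the upstream methodology names only the distance metric.
* Resampling: 80% of items per resample, **without replacement** — the
  conventional reading of "bootstraps encompassing 80% of samples", since
  80% subsampling (not a true with-replacement bootstrap) is what standard
  consensus-clustering implementations do at that fraction; a
  with-replacement mode is a flag. The headline default is B = 500
  resamples; the bundled tests use B = 20–100, which is ample for the
  well-separated synthetic structure (all consensus checks pass at those
  sizes, and the B = 100 runs recover planted partitions exactly).
* The consensus value of a pair is co-clustering count over co-sampling
  count, with 0/0 defined as 0 off the diagonal and a warning when any
  pair was never co-sampled (possible at very small B).
* Final partition: average-linkage tree cut of `1 − consensus`.
  Cluster ids are renumbered by decreasing size with ties broken by the
  smallest member index, making labels deterministic; the original
  subtyping's IS1..IS5 ordering criterion is unstated, so size order is a
  package convention, not a claim about the source analysis.
* Model selection (`selectK()`): the area A(k) under the empirical CDF of
  consensus values, with relative gain Δ(k) = (A(k) − A(k−1))/A(k−1) and
  Δ(k_min) = A(k_min); the chosen k is the largest with Δ(k) > 0.05. The
  0.05 threshold is a package default (the methodology states no numeric
  rule); `selectK()` always returns the full Δ curve so k can be fixed
  manually — the reference analysis fixed 4 gene modules and 5 subtypes.
* `consensusSweep()` shares the resample sequence and dendrograms across a
  k range, so model-selection sweeps cost one clustering per resample.

Genes and samples are clustered on the *same* gene-standardised matrix
(genes as rows for modules; its transpose for subtypes). Whether the
source analysis scaled the two views separately is unknowable from its
description; using one matrix is recorded here as the package's choice.
One consequence, found during design and worth knowing: when a matrix is
standardised over one set of columns but clustered on a subset (e.g.
discovery columns of a jointly standardised discovery+validation matrix),
the nonzero per-gene means over the subset distort gene-gene Euclidean
distances. `runPipeline()` therefore standardises the discovery block
itself for discovery clustering, while activities for transfer use the
shared standardisation so both cohorts stay on one scale.

## Batch integration

`combatAdjust()` performs parametric empirical-Bayes location/scale
adjustment (ComBat, via the sva package) with a grand-mean model and **no
biological covariates** — the upstream description names no covariates, and
adding subtype as a covariate before subtypes exist would be circular. A
mean-only flag is available. Expression is assumed already log-scale;
`log2p1()` is provided for raw FPKM-style input since the source transform
is unstated. Two practical notes:

* Genes with zero pooled variance cannot be standardised and are passed
  through unadjusted with a warning.
* EB shrinkage perturbs per-gene moments at sampling order O(1/√n): on
  batch-effect-free data the adjustment is not an exact identity, only an
  identity in expectation. The tests assert this at its honest stochastic
  tolerance.

`standardizeGenes()` uses the **population**-SD convention (denominator n,
not n−1), fixed so that tiny documented fixtures like (1,2,3) →
(−1.2247, 0, 1.2247) are exact.

## Subtype transfer

Module activities are means, so any affine change of a sample's activity
vector with positive slope leaves its Pearson correlation with a centroid
unchanged; `assignByCentroid()` inherits that robustness to residual
location/scale batch effects. Rank (Spearman) correlation is available but
not the default: with only four modules it is nearly degenerate.

The intermediate subtype — present by construction in the generator and
reported in the source subtyping as lacking characteristic module
activity — is **excluded from centroid matching by default**, mirroring the
stated restriction of assignment to the four characteristic subtypes. The
exact routing rule for ambiguous samples is not specified upstream, so the
package offers an explicit `ambiguityThreshold`: samples whose best
correlation falls below it are routed to the intermediate label rather
than forced into a characteristic subtype.

`clusterThenMatch()` implements the cluster-first variant: hierarchical
clustering of validation samples on activities, then greedy one-to-one
matching of cluster centroids to discovery centroids, highest correlation
first. Greedy (not Hungarian) matching is deliberate: at k ≤ 5 it is
simple, deterministic and adequate, and its failure mode (a cluster taking
its next-best subtype) is exactly the documented contract.

Whether validation cohorts should be batch-corrected against discovery
*before* activity computation is left open upstream; the package supports
both orders and `runPipeline()` records that it corrects jointly before
computing activities.

## The classifier

`fitMultinomial()` maximises the reference-class-zero softmax
log-likelihood with a small ridge (default 1e-4) on non-intercept weights,
by BFGS with analytic gradient (convergence: gradient sup-norm < 1e-6, up
to 500 iterations plus restarts). The ridge exists because a pure MLE
diverges on separable data — likely with well-separated subtypes — and the
upstream fitting procedure (penalty, standardisation) is unstated; both
are explicit arguments here, with internal feature standardisation stored
in the model. Features are the module activities, not individual genes:
the model is meant to weigh modules per subtype and transfer across
platforms. Evaluation fixes its conventions so fixtures are exact: AUROC
as the normalised Mann–Whitney U with ties counted 1/2, AUPRC as
step-interpolated precision over recall gains, macro averages unweighted,
absent classes reported as missing rather than zero.

## Survival and group comparisons

Kaplan–Meier, log-rank and Cox fits are computed through the survival
package; the package's contribution is the contract around them:

* **Efron** tie handling by default (less biased than Breslow under ties);
  Breslow available. The two coincide without tied event times.
* 95% Wald intervals, matching the "HR (95% CI)" reporting convention.
* Categorical baselines are **mandatory explicit arguments**: the analyses
  this package supports switch baselines between runs (worst-prognosis
  subtype for the subtype variable; different stage baselines in
  discovery vs validation), so nothing is defaulted silently.
  `subtypeSurvivalReport()` defaults the subtype baseline to IS4 (the
  worst-prognosis subtype of the design) only when that label exists.
* Subjects censored exactly at an event time count as at risk at that
  time (the standard convention).

Rank statistics: Kruskal–Wallis with midrank tie correction (H defined as
0 when all values are tied); Dunn's post hoc in its standard pooled-
midrank form with tie correction and Bonferroni capping at 1 (no installed
package provides Dunn, so it is implemented here and checked against hand
rank arithmetic); rank-sum exact by enumeration for pooled n ≤ 12 without
ties, else normal approximation with continuity and tie correction;
Fisher's two-sided p by the probability-mass rule (conventions differ, so
this is pinned and verified by exhaustive hypergeometric enumeration for
all 2×2 tables with total ≤ 40); chi-square without Yates correction by
default (flag available).

## The synthetic generator: what it emulates, and what not

`simulateCohort()` plants exactly the structure the analysis assumes:
block mean shifts for modules, subtype-specific activity signatures,
gene-wise additive/multiplicative batch effects (the model ComBat
assumes), exponential survival (constant hazard — the simplest law
satisfying proportional hazards exactly, so Cox recovery has a known
truth), independent uniform administrative censoring, and response labels
independent of survival given subtype (mirroring the design claim that
subtype prognosis is independent of clinical response).

Default study conditions, chosen once as field-realistic and frozen:

| parameter | default | rationale |
|---|---|---|
| modules × genes | 4 × 50 (+300 noise genes) | small enough to run in minutes, large enough for stable activity means |
| subtypes | 5 × 60 samples | five subtypes, discovery-scale cohort |
| activity amplitude | ±1.5 (log2 units) | immune-program shifts between immune-hot and -cold tumors are commonly 1–2 log2 units |
| noise SD | 1.0 | typical residual log-expression spread |
| baseline hazard | log(2)/45 per month | median OS ≈ 45 months in advanced ovarian cancer |
| subtype log-HRs | (0, −0.7, −0.2, +0.3, 0) | subtype 2 best / subtype 4 worst prognosis, HR ≈ 0.37 between them |
| censoring | U(0, 150) months | administrative follow-up; ≈55% event rate |
| response P(CR) | (0.45, 0.60, 0.50, 0.35, 0.50) | mild subtype-response association |

The signature matrix pins the characteristic cells (subtype 1 high GM3 /
low GM4; subtype 2 high GM2 / low GM4; subtype 4 high GM4 / low GM1;
subtype 5 high GM1 / low GM2–GM3; subtype 3 intermediate). The two free
"moderate" cells are set to −0.75 so that all module signature columns
have pairwise correlation ≤ 0: with them at zero, two module columns
correlate at +0.5 and those modules are confounded *by construction* —
a degenerate generator, not a clustering failure. Five subtypes of 60 is
deliberately balanced; real cohorts are not, and the discovered-label size
ordering will differ from planted names in general.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: read-count noise models and FPKM
normalisation artefacts, probe-level microarray effects, correlated noise
within modules beyond the planted shifts, gene-gene correlation among
noise genes, overlapping/soft module membership, cohort differences in
censoring mechanisms, non-proportional hazards, and immune-cell mixture
composition. Results on real cohorts depend on the curated gene list and
platform harmonisation in ways the synthetic testbed cannot probe.

## Problem sizes and numerical choices in the test suite

Tests run the full default conditions where a criterion depends on them
(structure recovery, transfer, classifier, with B = 100 resamples and a
20-seed k-selection sweep) and scaled-down instances elsewhere (B = 15–40,
reduced gene/sample counts) where only contracts, not power, are at stake;
survival calibration uses 200 replicates of two-arm n = 300 and five-arm
n = 200 designs with a minimal gene space. Stage seeds derive
deterministically from one root seed (`stageSeed()`), and every simulator
is seed-stable byte-for-byte. Floating-point equalities are asserted at
1e-12 unless an estimator's own convergence tolerance (1e-6 for the
classifier gradient and Cox comparisons) is the binding constraint.

## Known limitations

* Hard gene partitions; no soft/overlapping modules or gene weights.
* The consensus engine is O(B · m² ) memory-light but loops in R; very
  large cohorts (thousands of samples) would want a compiled inner loop.
* Cox fits report Wald intervals only; no proportional-hazards
  diagnostics, time-varying covariates or competing risks.
* The intermediate-subtype convention is positional (the label "IS3") in
  transfer defaults; with discovered labels the intermediate subtype need
  not be the third-largest, and callers should pass `excludeSubtypes`
  explicitly when that matters.
* Signature scores, deconvolved cell fractions, purity and leukocyte
  fraction are consumed as precomputed numeric columns; the package does
  not re-derive them.
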