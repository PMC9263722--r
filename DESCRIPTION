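Package: ImmuneSubtypes
Title: Immune Subtyping of Tumor Expression Cohorts by Consensus Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery and cross-cohort transfer of tumor immune subtypes from
    bulk expression data. Implements bootstrap consensus clustering of
    immune-related genes (gene modules) and samples (immune subtypes) with
    consensus-CDF model selection, empirical-Bayes batch integration of
    cohorts, gene-module activity scoring, centroid-correlation and
    multinomial-logistic subtype transfer with one-vs-rest ROC/PR evaluation,
    and survival association machinery (Kaplan-Meier, log-rank, Cox
    proportional hazards) together with rank-based group comparisons
    (Kruskal-Wallis with Dunn-Bonferroni post hoc, rank-sum, Fisher and
    chi-square tests). A seeded synthetic-cohort generator with planted
    modules, subtypes, batch effects and proportional-hazards survival
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    sva,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    nnet,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Clustering, Classification, Survival, BatchEffect
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ImmuneSubtypes-package.R'
    'utils.R'
    'activity.R'
    'classifier.R'
    'consensus.R'
    'survival.R'
    'features.R'
    'preprocess.R'
    'simulate.R'
    'pipeline.R'
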