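#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Cohort expression container
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one log-scale
#' gene-by-sample expression assay named `"exprs"`, a mandatory `cohort`
#' column in `colData`, and (optionally) per-sample survival columns
#' (`osTime`, `osEvent`), a `response` label, and planted ground truth from
#' the synthetic generator (`subtype` in `colData`, `module` in `rowData`,
#' `plantedCentroids` / `logHazards` in `metadata`).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        x <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(x) || any(!is.finite(x)))
            msg <- c(msg, "assay 'exprs' must be finite numeric")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (!"cohort" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'cohort' column")
    if (length(msg)) msg else TRUE
})

#' Construct a CohortExperiment from an expression matrix
#'
#' @param exprs numeric gene-by-sample matrix (log scale) with rownames
#'   (gene symbols) and colnames (sample ids).
#' @param cohort a single cohort label recycled to all samples, or one label
#'   per sample.
#' @param colData optional extra per-sample columns (data.frame or DataFrame).
#' @param rowData optional per-gene columns.
#' @param metadata optional list of cohort-level metadata.
#' @return a [CohortExperiment-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ce <- CohortExperiment(m, cohort = "disc")
#' @export
CohortExperiment <- function(exprs, cohort, colData = NULL, rowData = NULL,
                             metadata = list()) {
    exprs <- as.matrix(exprs)
    cohort <- rep_len(as.character(cohort), ncol(exprs))
    cd <- DataFrame(cohort = cohort, row.names = colnames(exprs))
    if (!is.null(colData)) {
        extra <- DataFrame(colData)
        extra$cohort <- NULL
        cd <- cbind(cd, extra)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs), colData = cd, metadata = metadata)
    if (!is.null(rowData))
        SummarizedExperiment::rowData(se) <- DataFrame(rowData)
    new("CohortExperiment", se)
}

#' Consensus clustering evidence for one cluster count
#'
#' Holds the pair-normalised consensus matrix for a single `k` together with
#' the raw co-cluster / co-sample counts, the final tree-cut labels, and the
#' empirical CDF of consensus values with its area (used for model
#' selection).
#'
#' @slot k integer cluster count.
#' @slot consensus symmetric item-by-item matrix in \[0,1\], unit diagonal.
#' @slot coClusterCounts integer matrix: resamples in which a pair co-clustered.
#' @slot coSampleCounts integer matrix: resamples in which a pair co-appeared.
#' @slot labels named integer vector, cluster id per item (sizes decreasing).
#' @slot cdfGrid data.frame with columns `consensus` and `cdf`.
#' @slot areaUnderCDF numeric scalar, trapezoid area of the CDF.
#' @slot scheme list echoing the resampling scheme used.
#' @export
setClass("ConsensusResult", representation(
    k = "integer", consensus = "matrix",
    coClusterCounts = "matrix", coSampleCounts = "matrix",
    labels = "integer", cdfGrid = "data.frame",
    areaUnderCDF = "numeric", scheme = "list"))

setValidity("ConsensusResult", function(object) {
    msg <- character()
    cm <- object@consensus
    if (nrow(cm) != ncol(cm)) msg <- c(msg, "consensus must be square")
    if (any(cm < -1e-12 | cm > 1 + 1e-12)) msg <- c(msg, "consensus outside [0,1]")
    if (max(abs(cm - t(cm))) > 1e-12) msg <- c(msg, "consensus not symmetric")
    if (any(abs(diag(cm) - 1) > 1e-12)) msg <- c(msg, "consensus diagonal must be 1")
    if (any(object@coClusterCounts > object@coSampleCounts))
        msg <- c(msg, "co-cluster counts exceed co-sample counts")
    if (length(msg)) msg else TRUE
})

#' Gene-to-module assignment
#'
#' @slot moduleOfGene named integer vector; `NA` for genes in no module.
#' @slot nModules integer number of modules (ids contiguous from 1).
#' @export
setClass("ModuleSet", representation(moduleOfGene = "integer",
                                     nModules = "integer"))

setValidity("ModuleSet", function(object) {
    m <- object@moduleOfGene
    msg <- character()
    if (is.null(names(m)) || anyDuplicated(names(m)))
        msg <- c(msg, "module map needs unique gene names")
    ids <- sort(unique(m[!is.na(m)]))
    if (length(ids) && !identical(ids, seq_len(object@nModules)))
        msg <- c(msg, "module ids must be contiguous 1..nModules")
    if (length(msg)) msg else TRUE
})

#' Sample-to-subtype assignment with provenance
#'
#' @slot subtype named factor, one subtype label per sample.
#' @slot provenance character: how each label was obtained, one of
#'   `"discovery"`, `"centroid"`, `"cluster_match"`, `"classifier"`, `"truth"`;
#'   recycled per sample.
#' @export
setClass("SubtypeLabels", representation(subtype = "factor",
                                         provenance = "character"))

setValidity("SubtypeLabels", function(object) {
    msg <- character()
    if (is.null(names(object@subtype)) || anyDuplicated(names(object@subtype)))
        msg <- c(msg, "subtype labels need unique sample names")
    ok <- c("discovery", "centroid", "cluster_match", "classifier", "truth")
    if (!all(object@provenance %in% ok))
        msg <- c(msg, sprintf("provenance must be one of %s",
                              paste(ok, collapse = ", ")))
    if (!length(object@provenance) %in% c(1L, length(object@subtype)))
        msg <- c(msg, "provenance must be length 1 or one per sample")
    if (length(msg)) msg else TRUE
})

#' Subtype centroids of module activities
#'
#' @slot centroids subtype-by-module numeric matrix of mean activities.
#' @slot sourceCohort label of the cohort the centroids were trained on.
#' @export
setClass("CentroidModel", representation(centroids = "matrix",
                                         sourceCohort = "character"))

setValidity("CentroidModel", function(object) {
    if (any(!is.finite(object@centroids))) "centroids must be finite" else TRUE
})

#' Multinomial logistic subtype classifier
#'
#' Reference-class-zero softmax model on (internally standardised) module
#' activities, fitted by penalised maximum likelihood.
#'
#' @slot classIds character, reference class first.
#' @slot featureIds character module ids.
#' @slot coefficients (nClasses-1) x (nFeatures+1) matrix, column 1 the
#'   intercept; log-odds of each non-reference class vs the reference.
#' @slot center,scale standardisation constants applied to features.
#' @slot ridge penalty used on non-intercept weights.
#' @slot converged logical.
#' @slot meta list (training cohort, n).
#' @export
setClass("MultinomialModel", representation(
    classIds = "character", featureIds = "character",
    coefficients = "matrix", center = "numeric", scale = "numeric",
    ridge = "numeric", converged = "logical", meta = "list"))

setValidity("MultinomialModel", function(object) {
    msg <- character()
    if (!identical(dim(object@coefficients),
                   c(length(object@classIds) - 1L,
                     length(object@featureIds) + 1L)))
        msg <- c(msg, "coefficient grid must be (nClasses-1) x (nFeatures+1)")
    if (length(msg)) msg else TRUE
})

#' Kaplan-Meier product-limit curve
#'
#' @slot time distinct event times, ascending.
#' @slot survival product-limit estimates at those times.
#' @slot nRisk,nEvent at-risk and event counts per time.
#' @slot group optional group label the curve belongs to.
#' @slot allCensored logical flag: no events observed.
#' @export
setClass("KMCurve", representation(
    time = "numeric", survival = "numeric", nRisk = "numeric",
    nEvent = "numeric", group = "character", allCensored = "logical"))

setValidity("KMCurve", function(object) {
    msg <- character()
    if (is.unsorted(object@time)) msg <- c(msg, "times must be ascending")
    if (any(diff(c(1, object@survival)) > 1e-12))
        msg <- c(msg, "survival must be non-increasing from 1")
    if (length(msg)) msg else TRUE
})

#' Cox proportional-hazards fit summary
#'
#' @slot table data.frame with one row per covariate level: `term`, `logHR`,
#'   `se`, `HR`, `ciLower`, `ciUpper`, `p`, `unstable`.
#' @slot ties tie-handling method (`"efron"` or `"breslow"`).
#' @slot n,nEvents sample and event counts.
#' @slot fit the underlying [survival::coxph] object.
#' @export
setClass("CoxFit", representation(table = "data.frame", ties = "character",
                                  n = "integer", nEvents = "integer",
                                  fit = "ANY"))

setValidity("CoxFit", function(object) {
    tab <- object@table
    need <- c("term", "logHR", "se", "HR", "ciLower", "ciUpper", "p")
    if (!all(need %in% colnames(tab))) "CoxFit table missing columns" else TRUE
})
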