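#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 result classes: slot access
#' is never needed from user code.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprs", function(x) standardGeneric("exprs"))
#' @rdname accessors
#' @export
setMethod("exprs", "CohortExperiment",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("cohortOf", function(x) standardGeneric("cohortOf"))
#' @rdname accessors
#' @export
setMethod("cohortOf", "CohortExperiment", function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$cohort, colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))
#' @rdname accessors
#' @export
setMethod("consensus", "ConsensusResult", function(x) x@consensus)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("areaUnderCDF", function(x) standardGeneric("areaUnderCDF"))
#' @rdname accessors
#' @export
setMethod("areaUnderCDF", "ConsensusResult", function(x) x@areaUnderCDF)

#' @rdname accessors
#' @export
setGeneric("moduleOf", function(x) standardGeneric("moduleOf"))
#' @rdname accessors
#' @export
setMethod("moduleOf", "ModuleSet", function(x) x@moduleOfGene)

#' @rdname accessors
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))
#' @rdname accessors
#' @export
setMethod("nModules", "ModuleSet", function(x) x@nModules)

#' @rdname accessors
#' @export
setGeneric("subtypeOf", function(x) standardGeneric("subtypeOf"))
#' @rdname accessors
#' @export
setMethod("subtypeOf", "SubtypeLabels", function(x) x@subtype)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "SubtypeLabels", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setMethod("centroids", "CentroidModel", function(x) x@centroids)

#' @rdname accessors
#' @export
setGeneric("coefficientsOf", function(x) standardGeneric("coefficientsOf"))
#' @rdname accessors
#' @export
setMethod("coefficientsOf", "MultinomialModel", function(x) x@coefficients)

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
#' @rdname accessors
#' @export
setMethod("resultTable", "CoxFit", function(x) x@table)

setMethod("show", "CohortExperiment", function(object) {
    callNextMethod()
    cat("cohorts:", paste(unique(cohortOf(object)), collapse = ", "), "\n")
})

setMethod("show", "ConsensusResult", function(object) {
    cat(sprintf("ConsensusResult: %d items, k = %d, %d resamples (fraction %.2f)\n",
                nrow(object@consensus), object@k,
                object@scheme$nBoot %||% NA_integer_,
                object@scheme$itemFraction %||% NA_real_))
    cat(sprintf("  area under consensus CDF: %.4f\n", object@areaUnderCDF))
    cat("  cluster sizes:",
        paste(tabulate(object@labels), collapse = ", "), "\n")
})

setMethod("show", "ModuleSet", function(object) {
    sizes <- tabulate(object@moduleOfGene[!is.na(object@moduleOfGene)],
                      nbins = object@nModules)
    cat(sprintf("ModuleSet: %d modules over %d genes (%d unassigned)\n",
                object@nModules, length(object@moduleOfGene),
                sum(is.na(object@moduleOfGene))))
    cat("  sizes:", paste(sizes, collapse = ", "), "\n")
})

setMethod("show", "SubtypeLabels", function(object) {
    cat(sprintf("SubtypeLabels: %d samples (%s)\n", length(object@subtype),
                paste(unique(object@provenance), collapse = "/")))
    print(table(object@subtype))
})

setMethod("show", "CentroidModel", function(object) {
    cat(sprintf("CentroidModel from cohort '%s'\n", object@sourceCohort))
    print(round(object@centroids, 3))
})

setMethod("show", "MultinomialModel", function(object) {
    cat(sprintf(
        "MultinomialModel: %d classes (reference %s), %d features, ridge %g%s\n",
        length(object@classIds), object@classIds[1],
        length(object@featureIds), object@ridge,
        if (object@converged) "" else " [NOT CONVERGED]"))
})

setMethod("show", "KMCurve", function(object) {
    cat(sprintf("KMCurve%s: %d event times%s\n",
                if (length(object@group)) paste0(" [", object@group, "]") else "",
                length(object@time),
                if (object@allCensored) " (all censored)" else ""))
})

setMethod("show", "CoxFit", function(object) {
    cat(sprintf("CoxFit (%s ties): n = %d, events = %d\n",
                object@ties, object@n, object@nEvents))
    print(object@table, digits = 3, row.names = FALSE)
})
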