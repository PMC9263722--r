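#' @include AllClasses.R utils.R
NULL

#' Restrict a curated gene set to genes measured in every cohort
#'
#' Intersects the immune gene list with the gene space of each cohort, in a
#' stable (sorted) order, reporting per-cohort retention.
#'
#' @param matrices list of [CohortExperiment-class] objects.
#' @param immuneGenes character vector of curated gene symbols (no
#'   duplicates).
#' @return sorted character vector of genes present in the curated set and
#'   in every cohort.
#' @export
curateGenes <- function(matrices, immuneGenes) {
    if (!length(matrices)) stop("at least one expression matrix is required")
    immuneGenes <- as.character(immuneGenes)
    if (!length(immuneGenes) || anyDuplicated(immuneGenes))
        stop("immune gene set must be non-empty without duplicates")
    keep <- immuneGenes
    for (i in seq_along(matrices)) {
        keep2 <- intersect(keep, rownames(matrices[[i]]))
        label <- unique(cohortOf(matrices[[i]]))[1]
        message(sprintf("curateGenes: %d/%d genes retained after cohort '%s'",
                        length(keep2), length(keep), label))
        if (!length(keep2))
            stop(sprintf("no curated genes left after intersecting cohort '%s'",
                         label))
        keep <- keep2
    }
    sort(keep)
}

#' Column-concatenate cohorts on a shared gene set
#'
#' @param matrices list of [CohortExperiment-class] objects.
#' @param genes genes to keep, present in every cohort.
#' @return a single [CohortExperiment-class]; cohort labels preserved, any
#'   shared `colData` columns carried along.
#' @export
mergeCohorts <- function(matrices, genes) {
    stopifnot(length(matrices) >= 1)
    genes <- as.character(genes)
    for (m in matrices) {
        miss <- setdiff(genes, rownames(m))
        if (length(miss))
            stop(sprintf("gene(s) %s missing from cohort '%s'",
                         paste(utils::head(miss, 3), collapse = ", "),
                         unique(cohortOf(m))[1]))
    }
    ids <- unlist(lapply(matrices, colnames))
    if (anyDuplicated(ids))
        stop("duplicate sample ids across cohorts: ",
             paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
    x <- do.call(cbind, lapply(matrices, function(m) exprs(m)[genes, , drop = FALSE]))
    shared <- Reduce(intersect, lapply(matrices, function(m)
        colnames(SummarizedExperiment::colData(m))))
    cd <- do.call(rbind, lapply(matrices, function(m)
        as.data.frame(SummarizedExperiment::colData(m))[, shared, drop = FALSE]))
    CohortExperiment(x, cohort = cd$cohort, colData = cd)
}

#' Empirical-Bayes batch correction
#'
#' Removes per-cohort location/scale batch effects with parametric ComBat
#' (grand-mean model, no biological covariates), via [sva::ComBat()]. With a
#' single batch the input is returned unchanged. Genes with zero pooled
#' variance cannot be standardised and are passed through unadjusted with a
#' warning.
#'
#' @param expr a [CohortExperiment-class].
#' @param batch batch label per sample (default: the cohort labels).
#' @param meanOnly adjust locations only (no scale shrinkage).
#' @return a [CohortExperiment-class] with identical dimensions and ids.
#' @export
combatAdjust <- function(expr, batch = cohortOf(expr), meanOnly = FALSE) {
    stopifnot(is(expr, "CohortExperiment"))
    batch <- as.character(rep_len(batch, ncol(expr)))
    if (length(unique(batch)) < 2L) return(expr)
    if (any(table(batch) < 2L))
        stop("each batch needs at least 2 samples")
    x <- exprs(expr)
    constant <- apply(x, 1, stats::var) <= 0
    if (any(constant))
        warning(sum(constant), " zero-variance gene(s) passed through unadjusted")
    xa <- x
    if (any(!constant)) {
        adj <- suppressMessages(sva::ComBat(
            dat = x[!constant, , drop = FALSE], batch = batch,
            mod = NULL, par.prior = TRUE, mean.only = meanOnly))
        xa[!constant, ] <- adj
    }
    out <- expr
    SummarizedExperiment::assay(out, "exprs") <- xa
    out
}

#' Z-score gene rows (population-SD convention)
#'
#' Centres every gene to mean 0 and scales to SD 1, dividing by the
#' population SD (denominator n) so that small fixtures have exact closed
#' forms. Zero-variance genes are dropped with a warning.
#'
#' @param expr a [CohortExperiment-class].
#' @return a [CohortExperiment-class], possibly with fewer genes.
#' @export
standardizeGenes <- function(expr) {
    stopifnot(is(expr, "CohortExperiment"))
    x <- exprs(expr)
    mu <- rowMeans(x)
    sdPop <- sqrt(rowMeans((x - mu)^2))
    drop <- sdPop <= 0
    if (any(drop))
        warning("dropping ", sum(drop), " constant gene(s): ",
                paste(utils::head(rownames(x)[drop], 3), collapse = ", "))
    x <- (x - mu) / sdPop
    out <- expr[!drop, ]
    SummarizedExperiment::assay(out, "exprs") <- x[!drop, , drop = FALSE]
    out
}

#' Apply log2(x + 1) to raw-scale input
#'
#' Convenience for FPKM-style matrices supplied on the raw scale.
#'
#' @param expr a [CohortExperiment-class] with non-negative values.
#' @return a [CohortExperiment-class] on the log2 scale.
#' @export
log2p1 <- function(expr) {
    x <- exprs(expr)
    if (any(x < 0)) stop("log2p1 expects non-negative raw-scale values")
    SummarizedExperiment::assay(expr, "exprs") <- log2(x + 1)
    expr
}
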