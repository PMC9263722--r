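#' @include AllClasses.R utils.R
NULL

#' Gene-module activity scores
#'
#' Activity of a module in a sample is the arithmetic mean expression of the
#' module's genes — the transferable 4-dimensional summary used for subtype
#' assignment and classification.
#'
#' @param expr a [CohortExperiment-class] (or plain gene-by-sample matrix).
#' @param modules a [ModuleSet-class], or a named integer vector gene ->
#'   module id.
#' @return module-by-sample numeric matrix, rows `GM1..GMk`.
#' @export
moduleActivity <- function(expr, modules) {
    x <- if (is(expr, "CohortExperiment")) exprs(expr) else as.matrix(expr)
    map <- if (is(modules, "ModuleSet")) moduleOf(modules) else modules
    map <- map[!is.na(map)]
    nMod <- max(map)
    act <- matrix(NA_real_, nMod, ncol(x),
                  dimnames = list(paste0("GM", seq_len(nMod)), colnames(x)))
    for (m in seq_len(nMod)) {
        genes <- intersect(names(map)[map == m], rownames(x))
        if (!length(genes))
            stop(sprintf("module %d has no genes in the expression matrix", m))
        act[m, ] <- colMeans(x[genes, , drop = FALSE])
    }
    act
}

#' Per-subtype centroids of module activities
#'
#' @param activity module-by-sample matrix from [moduleActivity()].
#' @param labels a [SubtypeLabels-class] (or named factor/character) over
#'   the same samples.
#' @param sourceCohort label recorded on the model.
#' @return a [CentroidModel-class]: subtype-by-module matrix of mean
#'   activities.
#' @export
subtypeCentroids <- function(activity, labels, sourceCohort = "discovery") {
    lab <- if (is(labels, "SubtypeLabels")) subtypeOf(labels) else labels
    nm <- names(lab)
    lab <- factor(as.character(lab))
    names(lab) <- nm
    if (!is.null(names(lab))) {
        if (!all(colnames(activity) %in% names(lab)))
            stop("labels missing for some samples")
        lab <- lab[colnames(activity)]
    } else if (length(lab) != ncol(activity)) {
        stop("labels must cover every sample")
    }
    if (any(is.na(lab))) stop("every sample needs a subtype label")
    lab <- droplevels(lab)
    if (any(table(lab) == 0)) stop("empty subtype in labels")
    cent <- t(vapply(levels(lab), function(l)
        rowMeans(activity[, lab == l, drop = FALSE]),
        numeric(nrow(activity))))
    dimnames(cent) <- list(levels(lab), rownames(activity))
    new("CentroidModel", centroids = cent, sourceCohort = sourceCohort)
}

#' Assign subtypes by centroid correlation
#'
#' Each sample is assigned to the subtype whose centroid has the highest
#' Pearson correlation with the sample's module-activity vector. By default
#' the configured intermediate subtype's centroid is excluded from matching
#' (the study restricted assignment to the four characteristic subtypes
#' because the fifth lacked distinguishing module activity); samples whose
#' best correlation falls below `ambiguityThreshold` are routed to
#' `ambiguousLabel` instead.
#'
#' @param activity module-by-sample matrix for the new cohort.
#' @param model a [CentroidModel-class] from the discovery cohort.
#' @param excludeSubtypes centroids excluded from matching (default
#'   `"IS3"` when present; use `character(0)` to match against all).
#' @param ambiguityThreshold minimum best correlation; default `-1`
#'   (disabled).
#' @param ambiguousLabel label given to low-confidence samples (default the
#'   first excluded subtype, else `"ambiguous"`).
#' @param method correlation flavour, `"pearson"` (default) or
#'   `"spearman"`.
#' @return a [SubtypeLabels-class] with provenance `"centroid"`;
#'   zero-variance activity vectors get an `NA` label (flagged unassigned).
#' @export
assignByCentroid <- function(activity, model,
                             excludeSubtypes = intersect("IS3", rownames(centroids(model))),
                             ambiguityThreshold = -1,
                             ambiguousLabel = NULL,
                             method = c("pearson", "spearman")) {
    method <- match.arg(method)
    cent <- centroids(model)
    if (nrow(activity) < 3)
        stop("centroid correlation needs at least 3 modules")
    if (!setequal(rownames(activity), colnames(cent)))
        stop("module ids of activity and centroid model must match")
    cent <- cent[, rownames(activity), drop = FALSE]
    use <- setdiff(rownames(cent), excludeSubtypes)
    if (!length(use)) stop("no centroids left after exclusion")
    ambiguousLabel <- ambiguousLabel %||%
        (if (length(excludeSubtypes)) excludeSubtypes[1] else "ambiguous")

    sds <- apply(activity, 2, stats::sd)
    r <- matrix(NA_real_, length(use), ncol(activity),
                dimnames = list(use, colnames(activity)))
    ok <- sds > 0
    if (any(ok))
        r[, ok] <- stats::cor(cent[use, , drop = FALSE] |> t(),
                              activity[, ok, drop = FALSE], method = method)
    best <- apply(r, 2, function(v) if (all(is.na(v))) NA_integer_
                  else which.max(v))
    bestCor <- vapply(seq_len(ncol(r)), function(j)
        if (is.na(best[j])) NA_real_ else r[best[j], j], 0)
    lab <- ifelse(is.na(best), NA_character_, use[best])
    lab[!is.na(bestCor) & bestCor < ambiguityThreshold] <- ambiguousLabel
    levs <- unique(c(rownames(cent), ambiguousLabel))
    subtype <- factor(lab, levels = levs)
    names(subtype) <- colnames(activity)
    if (any(is.na(subtype)))
        warning(sum(is.na(subtype)),
                " sample(s) with zero-variance activity left unassigned")
    new("SubtypeLabels", subtype = subtype, provenance = "centroid")
}

#' Cluster validation samples, then match clusters to discovery centroids
#'
#' The study's first transfer route: hierarchically cluster the validation
#' cohort on module activities (Euclidean, average linkage) into `k`
#' clusters, compute cluster centroids, and match each cluster to the
#' discovery subtype with maximal Pearson correlation — greedily, highest
#' correlation first, each subtype used at most once unless `allowReuse`.
#' All samples of a cluster inherit its matched label.
#'
#' @inheritParams assignByCentroid
#' @param k number of validation clusters (must not exceed the sample
#'   count).
#' @param allowReuse let several clusters take the same subtype.
#' @return a [SubtypeLabels-class] with provenance `"cluster_match"`.
#' @export
clusterThenMatch <- function(activity, model, k = 4,
                             excludeSubtypes = intersect("IS3", rownames(centroids(model))),
                             allowReuse = FALSE) {
    cent <- centroids(model)
    if (nrow(activity) < 3)
        stop("centroid correlation needs at least 3 modules")
    if (!setequal(rownames(activity), colnames(cent)))
        stop("module ids of activity and centroid model must match")
    if (k > ncol(activity)) stop("k exceeds the number of samples")
    cent <- cent[, rownames(activity), drop = FALSE]
    use <- setdiff(rownames(cent), excludeSubtypes)

    cl <- renumberBySize(stats::cutree(
        stats::hclust(stats::dist(t(activity)), "average"), k = k))
    clCent <- vapply(seq_len(k), function(c)
        rowMeans(activity[, cl == c, drop = FALSE]), numeric(nrow(activity)))
    r <- stats::cor(cent[use, , drop = FALSE] |> t(), clCent)  # subtype x cluster

    match <- rep(NA_character_, k)
    rWork <- r
    for (step in seq_len(k)) {
        if (all(is.na(rWork)) || !any(is.finite(rWork))) break
        ij <- which(rWork == max(rWork, na.rm = TRUE), arr.ind = TRUE)[1, ]
        match[ij[2]] <- use[ij[1]]
        rWork[, ij[2]] <- NA
        if (!allowReuse) rWork[ij[1], ] <- NA
    }
    if (any(is.na(match)))
        stop("could not match every cluster to a subtype (k exceeds usable centroids?)")
    subtype <- factor(match[cl], levels = rownames(cent))
    names(subtype) <- colnames(activity)
    new("SubtypeLabels", subtype = subtype, provenance = "cluster_match")
}
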