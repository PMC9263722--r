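#' @include AllClasses.R utils.R
NULL

hclustMethod <- function(linkage) {
    switch(linkage, average = "average", complete = "complete",
           ward = "ward.D2",
           stop("linkage must be one of average, complete, ward"))
}

#' Subsampled consensus clustering for one cluster count
#'
#' Monti-style consensus: repeatedly subsample items, cluster each subsample
#' with agglomerative hierarchical clustering on Euclidean distance, cut at
#' `k`, and record for every item pair how often it was sampled together and
#' how often it co-clustered. The consensus matrix is the elementwise ratio
#' (0/0 defined as 0 off-diagonal, 1 on the diagonal). Item pairs never
#' co-sampled (possible at few resamples) trigger a warning.
#'
#' @param X item-by-feature numeric matrix; rows are clustered.
#' @param k cluster count, `2 <= k <= nrow(X)`.
#' @param nBoot number of resamples (the study default is 500; smaller
#'   values are adequate for well-separated structure).
#' @param itemFraction fraction of items drawn per resample (study default
#'   0.8). Drawn without replacement unless `withReplacement`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @param seed integer seed; results are deterministic given it.
#' @param withReplacement resample items with replacement instead.
#' @return a [ConsensusResult-class]; `labels` holds the final tree cut of
#'   `1 - consensus` (see [cutConsensus()]).
#' @examples
#' X <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 8), 10))
#' cr <- consensusCluster(X, k = 2, nBoot = 20, seed = 1)
#' table(clusterLabels(cr))
#' @export
consensusCluster <- function(X, k, nBoot = 500, itemFraction = 0.8,
                             linkage = c("average", "complete", "ward"),
                             seed = 1, withReplacement = FALSE) {
    consensusSweep(X, ks = k, nBoot = nBoot, itemFraction = itemFraction,
                   linkage = linkage, seed = seed,
                   withReplacement = withReplacement)[[1]]
}

#' Consensus clustering over a range of cluster counts
#'
#' Same resampling engine as [consensusCluster()], but every resample's
#' dendrogram is cut at all requested `ks`, so the per-pair sampling counts
#' (and the resample sequence) are shared across cluster counts. This is
#' the natural input to [selectK()]: the study swept k from 2 to 10.
#'
#' @inheritParams consensusCluster
#' @param ks integer vector of cluster counts.
#' @return named list of [ConsensusResult-class], one per `k` (names
#'   `"k=2"`, ...). `consensusSweep(X, ks = k, ...)[[1]]` is identical to
#'   `consensusCluster(X, k, ...)`.
#' @export
consensusSweep <- function(X, ks, nBoot = 500, itemFraction = 0.8,
                           linkage = c("average", "complete", "ward"),
                           seed = 1, withReplacement = FALSE) {
    X <- as.matrix(X)
    n <- nrow(X)
    ks <- as.integer(ks)
    if (any(ks < 2L)) stop("k must be at least 2")
    if (any(ks > n)) stop("k exceeds the number of items")
    if (ncol(X) < 1L) stop("at least one feature is required")
    if (itemFraction <= 0 || itemFraction > 1)
        stop("itemFraction must lie in (0, 1]")
    nBoot <- as.integer(nBoot)
    if (nBoot < 1L) stop("nBoot must be at least 1")
    linkage <- match.arg(linkage)
    method <- hclustMethod(linkage)
    m <- ceiling(itemFraction * n)

    coCluster <- lapply(ks, function(k) matrix(0, n, n))
    names(coCluster) <- as.character(ks)
    coSample <- matrix(0, n, n)
    withSeed(seed, {
        for (b in seq_len(nBoot)) {
            idx <- if (withReplacement) sample.int(n, m, replace = TRUE)
                   else sample.int(n, m)
            uidx <- unique(idx)
            hc <- stats::hclust(stats::dist(X[uidx, , drop = FALSE]), method)
            coSample[uidx, uidx] <- coSample[uidx, uidx] + 1
            for (ki in seq_along(ks)) {
                cl <- stats::cutree(hc, k = min(ks[ki], length(uidx)))
                for (c in unique(cl)) {
                    members <- uidx[cl == c]
                    coCluster[[ki]][members, members] <-
                        coCluster[[ki]][members, members] + 1
                }
            }
        }
    })
    if (any(coSample[upper.tri(coSample)] == 0))
        warning("some item pairs were never co-sampled; their consensus is 0")

    out <- lapply(seq_along(ks), function(ki) {
        cons <- ifelse(coSample > 0, coCluster[[ki]] / pmax(coSample, 1), 0)
        diag(cons) <- 1
        dimnames(cons) <- list(rownames(X), rownames(X))
        res <- new("ConsensusResult", k = ks[ki], consensus = cons,
                   coClusterCounts = coCluster[[ki]], coSampleCounts = coSample,
                   labels = integer(0), cdfGrid = data.frame(),
                   areaUnderCDF = NA_real_,
                   scheme = list(nBoot = nBoot, itemFraction = itemFraction,
                                 linkage = linkage, seed = seed,
                                 withReplacement = withReplacement))
        cdf <- consensusCDF(res)
        res@cdfGrid <- cdf$grid
        res@areaUnderCDF <- cdf$area
        res@labels <- cutConsensus(res, ks[ki])
        validObject(res)
        res
    })
    names(out) <- paste0("k=", ks)
    out
}

#' Empirical CDF of consensus values and its area
#'
#' CDF of the upper-triangle consensus entries evaluated on the grid
#' 0, 0.01, ..., 1; area by the trapezoid rule. The area grows towards 1 as
#' the consensus distribution concentrates at \{0, 1\}; its gain across `k`
#' drives [selectK()].
#'
#' @param result a [ConsensusResult-class].
#' @return list with `grid` (data.frame: `consensus`, `cdf`) and `area`.
#' @export
consensusCDF <- function(result) {
    v <- result@consensus[upper.tri(result@consensus)]
    grid <- seq(0, 1, by = 0.01)
    cdf <- stats::ecdf(v)(grid)
    area <- sum(diff(grid) * (utils::head(cdf, -1) + utils::tail(cdf, -1)) / 2)
    list(grid = data.frame(consensus = grid, cdf = cdf), area = area)
}

#' Choose the cluster count from consensus-CDF areas
#'
#' Relative delta-area rule: with `A(k)` the area under the consensus CDF,
#' `delta(kmin) = A(kmin)` and `delta(k) = (A(k) - A(k-1)) / A(k-1)` for
#' larger `k`; the chosen `k` is the largest whose relative gain exceeds
#' `threshold`. The full curve is returned so the call is advisory — the
#' cluster count can always be fixed manually (the study fixed 4 gene
#' modules and 5 subtypes).
#'
#' @param results list of [ConsensusResult-class] for consecutive `k`.
#' @param threshold minimum relative area gain (default 0.05).
#' @return list: `k` (chosen count), `curve` (data.frame `k`, `area`,
#'   `deltaArea`).
#' @export
selectK <- function(results, threshold = 0.05) {
    ks <- vapply(results, function(r) r@k, 0L)
    if (length(ks) < 2L || any(diff(sort(ks)) != 1L))
        stop("results must cover at least two consecutive k")
    ord <- order(ks)
    ks <- ks[ord]
    areas <- vapply(results[ord], areaUnderCDF, 0)
    delta <- c(areas[1], diff(areas) / utils::head(areas, -1))
    above <- which(delta > threshold)
    kChosen <- if (length(above)) ks[max(above)] else ks[1]
    list(k = kChosen,
         curve = data.frame(k = ks, area = areas, deltaArea = delta))
}

#' Final partition from a consensus matrix
#'
#' Average-linkage agglomerative clustering on the dissimilarity
#' `1 - consensus`, cut at `k`; cluster ids are renumbered by decreasing
#' size (ties: smallest member index) so labels are deterministic.
#'
#' @param result a [ConsensusResult-class].
#' @param k cluster count (default: the result's own `k`).
#' @return named integer vector of cluster ids.
#' @export
cutConsensus <- function(result, k = result@k) {
    n <- nrow(result@consensus)
    if (k > n) stop("k exceeds the number of items")
    hc <- stats::hclust(stats::as.dist(1 - result@consensus), "average")
    renumberBySize(stats::cutree(hc, k = k))
}

#' Discover gene modules and sample subtypes in one pass
#'
#' Runs [consensusCluster()] twice on a preprocessed, gene-standardised
#' matrix: once on gene rows (features = samples) to define gene modules,
#' once on sample columns (features = genes) to define subtypes. Partitions
#' are named `GM1..GMk` / `IS1..ISk` in decreasing size order.
#'
#' @param expr a [CohortExperiment-class] (merged, batch-corrected,
#'   standardised; see [standardizeGenes()]).
#' @param kGenes,kSamples cluster counts (study defaults 4 and 5); pass the
#'   output of [selectK()] to choose them from the data.
#' @param nBoot,itemFraction,linkage,seed as in [consensusCluster()].
#' @return list with `modules` ([ModuleSet-class]), `subtypes`
#'   ([SubtypeLabels-class], provenance `"discovery"`), `geneConsensus` and
#'   `sampleConsensus` ([ConsensusResult-class]).
#' @export
discoverSubtypes <- function(expr, kGenes = 4, kSamples = 5, nBoot = 500,
                             itemFraction = 0.8, linkage = "average",
                             seed = 1) {
    stopifnot(is(expr, "CohortExperiment"))
    x <- exprs(expr)
    gRes <- consensusCluster(x, k = kGenes, nBoot = nBoot,
                             itemFraction = itemFraction, linkage = linkage,
                             seed = stageSeed(seed, "genes"))
    sRes <- consensusCluster(t(x), k = kSamples, nBoot = nBoot,
                             itemFraction = itemFraction, linkage = linkage,
                             seed = stageSeed(seed, "samples"))
    modules <- new("ModuleSet",
                   moduleOfGene = gRes@labels, nModules = as.integer(kGenes))
    subtype <- factor(paste0("IS", sRes@labels),
                      levels = paste0("IS", seq_len(kSamples)))
    names(subtype) <- colnames(x)
    list(modules = modules,
         subtypes = new("SubtypeLabels", subtype = subtype,
                        provenance = "discovery"),
         geneConsensus = gRes, sampleConsensus = sRes)
}
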