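#' @include AllClasses.R utils.R
NULL

# Default subtype-by-module signature. Salient cells: subtype 1 high GM3 /
# low GM4, subtype 2 high GM2 / low GM4, subtype 4 high GM4 / low GM1,
# subtype 5 high GM1 / low GM2+GM3, subtype 3 intermediate throughout. The
# mild -0.75 entries keep the module signature columns mutually
# non-redundant (pairwise correlation <= 0), so no two modules encode the
# same co-expression program.
defaultActivityPattern <- function() {
    a <- 1.5
    p <- rbind(
        IS1 = c(0, -a / 2,  a, -a),
        IS2 = c(0,  a, -a / 2, -a),
        IS3 = c(0, 0, 0, 0),
        IS4 = c(-a, 0, 0,  a),
        IS5 = c(a, -a, -a, 0))
    colnames(p) <- paste0("GM", 1:4)
    p
}

#' Configuration of the synthetic two-cohort generator
#'
#' Defines the statistical structure the subtyping analysis assumes: gene
#' modules planted as block mean shifts, five subtypes with distinct
#' module-activity signatures (one deliberately intermediate, mirroring the
#' "no typical characteristics" subtype), gene-wise additive/multiplicative
#' cohort batch effects, exponential proportional-hazards survival and
#' Bernoulli treatment-response labels.
#'
#' @slot nModules number of gene modules.
#' @slot genesPerModule genes in each module.
#' @slot nNoiseGenes unstructured genes carrying no module signal.
#' @slot subtypeSizes samples per subtype.
#' @slot activityPattern subtype-by-module matrix of mean expression shifts
#'   (log-expression units) added to module genes.
#' @slot intermediateSubtype row index of the configured intermediate
#'   subtype, exempt from the pairwise-distinct-rows requirement.
#' @slot noiseSd Gaussian noise SD (log-expression units).
#' @slot batchSpecs named list: per cohort, `list(shift =, scale =)`, each a
#'   scalar or per-gene vector. Cohorts not listed get shift 0 / scale 1.
#' @slot baselineHazard events per month for the reference subtype.
#' @slot logHazardBySubtype per-subtype log hazard ratios.
#' @slot censorTimeMax administrative censoring drawn U(0, this) months.
#' @slot responseProbBySubtype P(complete response) per subtype.
#' @slot seed integer seed; gene-level baselines depend only on this, so
#'   cohorts generated from one config share their gene space.
#' @export
setClass("SimulationConfig", representation(
    nModules = "integer", genesPerModule = "integer", nNoiseGenes = "integer",
    subtypeSizes = "integer", activityPattern = "matrix",
    intermediateSubtype = "integer", noiseSd = "numeric",
    batchSpecs = "list", baselineHazard = "numeric",
    logHazardBySubtype = "numeric", censorTimeMax = "numeric",
    responseProbBySubtype = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (any(c(object@nModules, object@genesPerModule) < 1L) ||
        object@nNoiseGenes < 0L || any(object@subtypeSizes < 1L))
        msg <- c(msg, "counts must be positive (noise genes may be 0)")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    k <- length(object@subtypeSizes)
    if (sum(object@subtypeSizes) < 2L * k)
        msg <- c(msg, "subtype sizes must sum to at least 2 per subtype")
    p <- object@activityPattern
    if (any(!is.finite(p))) msg <- c(msg, "activity pattern must be finite")
    if (nrow(p) != k)
        msg <- c(msg, "activity pattern rows must match subtype count")
    if (ncol(p) != object@nModules)
        msg <- c(msg, "activity pattern columns must match module count")
    keep <- setdiff(seq_len(nrow(p)), object@intermediateSubtype)
    if (length(keep) > 1 && anyDuplicated(p[keep, , drop = FALSE]))
        msg <- c(msg, "non-intermediate activity rows must be pairwise distinct")
    if (length(object@logHazardBySubtype) != k ||
        length(object@responseProbBySubtype) != k)
        msg <- c(msg, "per-subtype hazard/response vectors must match subtype count")
    if (any(object@responseProbBySubtype < 0 | object@responseProbBySubtype > 1))
        msg <- c(msg, "response probabilities must lie in [0,1]")
    if (object@baselineHazard <= 0 || object@censorTimeMax <= 0)
        msg <- c(msg, "baselineHazard and censorTimeMax must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nModules,genesPerModule,nNoiseGenes,subtypeSizes,activityPattern
#'   see slots.
#' @param intermediateSubtype,noiseSd,batchSpecs,baselineHazard see slots.
#' @param logHazardBySubtype,censorTimeMax,responseProbBySubtype,seed see
#'   slots.
#' @return a validated `SimulationConfig`.
#' @details Defaults encode the study conditions the pipeline is tested
#'   under: 4 modules of 50 genes plus 300 noise genes; five subtypes of 60
#'   samples whose signature pattern follows the discovery-cohort boxplots
#'   (subtype 1 high module 3 / low module 4; subtype 2 high module 2 / low
#'   module 4; subtype 4 high module 4 / low module 1; subtype 5 high module
#'   1 / low modules 2-3; subtype 3 intermediate throughout); amplitude 1.5
#'   and noise SD 1 on the log scale; baseline hazard log(2)/45 per month
#'   (median overall survival about 45 months) with subtype log hazard
#'   ratios (0, -0.7, -0.2, 0.3, 0) so subtype 2 has the best and subtype 4
#'   the worst prognosis.
#' @export
simulationConfig <- function(nModules = 4, genesPerModule = 50,
                             nNoiseGenes = 300,
                             subtypeSizes = rep(60L, 5),
                             activityPattern = defaultActivityPattern(),
                             intermediateSubtype = 3L,
                             noiseSd = 1,
                             batchSpecs = list(
                                 validation = list(shift = 2, scale = 1)),
                             baselineHazard = log(2) / 45,
                             logHazardBySubtype = c(0, -0.7, -0.2, 0.3, 0),
                             censorTimeMax = 150,
                             responseProbBySubtype = c(0.45, 0.6, 0.5, 0.35, 0.5),
                             seed = 1L) {
    if (is.null(rownames(activityPattern)))
        rownames(activityPattern) <- paste0("IS", seq_len(nrow(activityPattern)))
    if (is.null(colnames(activityPattern)))
        colnames(activityPattern) <- paste0("GM", seq_len(ncol(activityPattern)))
    new("SimulationConfig",
        nModules = as.integer(nModules),
        genesPerModule = as.integer(genesPerModule),
        nNoiseGenes = as.integer(nNoiseGenes),
        subtypeSizes = as.integer(subtypeSizes),
        activityPattern = activityPattern,
        intermediateSubtype = as.integer(intermediateSubtype),
        noiseSd = noiseSd, batchSpecs = batchSpecs,
        baselineHazard = baselineHazard,
        logHazardBySubtype = logHazardBySubtype,
        censorTimeMax = censorTimeMax,
        responseProbBySubtype = responseProbBySubtype,
        seed = as.integer(seed))
}

# Gene-level quantities depend only on config@seed so that every cohort
# generated from one config lives in the same gene space.
geneBaseline <- function(config) {
    nGenes <- config@nModules * config@genesPerModule + config@nNoiseGenes
    module <- c(rep(seq_len(config@nModules), each = config@genesPerModule),
                rep(NA_integer_, config@nNoiseGenes))
    genes <- character(nGenes)
    gi <- 0L
    for (m in seq_len(config@nModules))
        for (j in seq_len(config@genesPerModule)) {
            gi <- gi + 1L
            genes[gi] <- sprintf("GM%d_G%03d", m, j)
        }
    if (config@nNoiseGenes > 0)
        genes[(gi + 1L):nGenes] <- sprintf("NOISE_G%03d",
                                           seq_len(config@nNoiseGenes))
    base <- withSeed(stageSeed(config@seed, "gene-baseline"),
                     stats::rnorm(nGenes, mean = 6, sd = 1.5))
    list(genes = genes, module = stats::setNames(module, genes),
         base = stats::setNames(base, genes))
}

resolveBatchSpec <- function(spec, nGenes) {
    spec <- spec %||% list()
    shift <- spec$shift %||% 0
    scale <- spec$scale %||% 1
    if (!length(shift) %in% c(1L, nGenes) || !length(scale) %in% c(1L, nGenes))
        stop("batch spec shift/scale must be scalar or one value per gene (",
             nGenes, " genes)")
    if (any(!is.finite(shift)) || any(!is.finite(scale)))
        stop("batch spec must be finite")
    list(shift = rep_len(shift, nGenes), scale = rep_len(scale, nGenes))
}

simulateCore <- function(config, cohortId, subtypeSizes, batchSpec, seed) {
    gl <- geneBaseline(config)
    nGenes <- length(gl$genes)
    bs <- resolveBatchSpec(batchSpec, nGenes)
    k <- nrow(config@activityPattern)
    subtype <- rep(seq_len(k), times = subtypeSizes)
    n <- length(subtype)
    if (n == 0L) stop("at least one sample must be requested")

    withSeed(seed, {
        act <- matrix(0, nGenes, n)
        inMod <- !is.na(gl$module)
        act[inMod, ] <- config@activityPattern[subtype, gl$module[inMod],
                                               drop = FALSE] |> t()
        x <- (gl$base + act + bs$shift) * bs$scale +
            matrix(stats::rnorm(nGenes * n, sd = config@noiseSd), nGenes, n)
        rate <- config@baselineHazard * exp(config@logHazardBySubtype[subtype])
        tEvent <- stats::rexp(n, rate = rate)
        tCens <- stats::runif(n, 0, config@censorTimeMax)
        osTime <- pmin(tEvent, tCens)
        osEvent <- as.integer(tEvent <= tCens)
        response <- ifelse(
            stats::rbinom(n, 1, config@responseProbBySubtype[subtype]) == 1,
            "CR", "nonCR")
    })

    sampleIds <- sprintf("%s_s%04d", cohortId, seq_len(n))
    dimnames(x) <- list(gl$genes, sampleIds)
    subtypeLab <- factor(rownames(config@activityPattern)[subtype],
                         levels = rownames(config@activityPattern))
    planted <- config@activityPattern +
        vapply(seq_len(config@nModules), function(m)
            rep(mean(gl$base[which(gl$module == m)]), k), numeric(k))
    dimnames(planted) <- dimnames(config@activityPattern)
    CohortExperiment(
        x, cohort = cohortId,
        colData = data.frame(subtype = subtypeLab, osTime = osTime,
                             osEvent = osEvent, response = response,
                             row.names = sampleIds),
        rowData = data.frame(module = gl$module, baseline = gl$base,
                             row.names = gl$genes),
        metadata = list(
            plantedCentroids = planted,
            plantedPattern = config@activityPattern,
            logHazards = stats::setNames(config@logHazardBySubtype,
                                         rownames(config@activityPattern)),
            seedUsed = seed))
}

#' Simulate a discovery-style cohort with planted structure
#'
#' Expression for gene g (module m) in sample s (subtype k, cohort b) is
#' `(baseline_g + pattern[k, m] + shift_bg) * scale_bg + N(0, noiseSd)`;
#' noise genes carry no pattern term. Survival times are exponential with
#' hazard `baselineHazard * exp(logHazard_k)`, censored by an independent
#' U(0, censorTimeMax) administrative time; the response label is
#' Bernoulli(responseProb_k). Fully deterministic given the config seed and
#' cohort id.
#'
#' @param config a [simulationConfig()].
#' @param cohortId cohort label; also keys into `batchSpecs` and the
#'   cohort-specific RNG stream.
#' @return a [CohortExperiment-class] whose `colData` carries the true
#'   subtype, survival and response columns and whose `rowData` carries the
#'   true module map (see [trueModules()], [trueSubtypes()],
#'   [plantedCentroids()], [survivalData()]).
#' @examples
#' ce <- simulateCohort(simulationConfig(subtypeSizes = rep(5L, 5)), "disc")
#' dim(ce)
#' @export
simulateCohort <- function(config, cohortId = "discovery") {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    simulateCore(config, cohortId, config@subtypeSizes,
                 config@batchSpecs[[cohortId]],
                 stageSeed(config@seed, paste0("cohort:", cohortId)))
}

#' Simulate a validation cohort sharing the discovery gene space
#'
#' Draws new samples from the same subtype signatures (same gene baselines
#' and activity pattern, hence the same planted centroids) under a different
#' batch effect, for testing label transfer.
#'
#' @inheritParams simulateCohort
#' @param batchShift,batchScale additive shift and multiplicative scale,
#'   scalar or per gene.
#' @param subtypeSizes optional new per-subtype sample counts (default: the
#'   config's).
#' @return a [CohortExperiment-class] with truth columns as in
#'   [simulateCohort()].
#' @export
simulateValidationCohort <- function(config, cohortId = "validation",
                                     batchShift = 2, batchScale = 1,
                                     subtypeSizes = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    subtypeSizes <- as.integer(subtypeSizes %||% config@subtypeSizes)
    if (sum(subtypeSizes) < 1L) stop("at least one sample must be requested")
    simulateCore(config, cohortId, subtypeSizes,
                 list(shift = batchShift, scale = batchScale),
                 stageSeed(config@seed, paste0("cohort:", cohortId)))
}

#' Ground-truth accessors for synthetic cohorts
#'
#' @param x a [CohortExperiment-class] produced by the simulator.
#' @return `trueModules`: a [ModuleSet-class]; `trueSubtypes`: a
#'   [SubtypeLabels-class] with provenance `"truth"`; `plantedCentroids`:
#'   the subtype-by-module activity means implied by the planted pattern
#'   (baseline included).
#' @name truth-accessors
#' @export
trueModules <- function(x) {
    m <- SummarizedExperiment::rowData(x)$module
    if (is.null(m)) stop("no planted module truth in this object")
    new("ModuleSet", moduleOfGene = stats::setNames(as.integer(m), rownames(x)),
        nModules = max(m, na.rm = TRUE))
}

#' @rdname truth-accessors
#' @export
trueSubtypes <- function(x) {
    s <- SummarizedExperiment::colData(x)$subtype
    if (is.null(s)) stop("no planted subtype truth in this object")
    new("SubtypeLabels",
        subtype = stats::setNames(factor(s), colnames(x)),
        provenance = "truth")
}

#' @rdname truth-accessors
#' @export
plantedCentroids <- function(x) {
    pc <- S4Vectors::metadata(x)$plantedCentroids
    if (is.null(pc)) stop("no planted centroids in this object")
    pc
}

#' Extract the per-sample survival/clinical table
#'
#' @param x a [CohortExperiment-class] with `osTime`/`osEvent` columns.
#' @return data.frame with `sample`, `time`, `event`, plus any of `cohort`,
#'   `subtype`, `response` present.
#' @export
survivalData <- function(x) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (!all(c("osTime", "osEvent") %in% colnames(cd)))
        stop("colData must contain osTime and osEvent")
    out <- data.frame(sample = colnames(x), time = cd$osTime,
                      event = cd$osEvent, row.names = colnames(x))
    for (col in c("cohort", "subtype", "response"))
        if (col %in% colnames(cd)) out[[col]] <- cd[[col]]
    out
}
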