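#' @include AllClasses.R simulate.R preprocess.R consensus.R activity.R
#' @include classifier.R survival.R features.R
NULL

#' Run the full subtyping analysis end-to-end
#'
#' Orchestrates the whole workflow on synthetic or user-supplied cohorts:
#' simulate (two discovery cohorts plus a batch-shifted validation cohort)
#' -> curate/merge -> batch-correct -> standardise -> consensus discovery of
#' gene modules and subtypes -> centroid and cluster-match transfer to the
#' validation cohort -> multinomial classifier with one-vs-rest evaluation
#' -> subtype survival report -> group comparisons. Every intermediate
#' table is written under `outDir` and listed, with an MD5 checksum, in
#' `manifest.json`; re-running with the same config and seed reproduces
#' identical label tables.
#'
#' @param config a [simulationConfig()] driving the synthetic cohorts
#'   (ignored for the expression inputs when `cohorts` is supplied).
#' @param outDir output directory (created if needed).
#' @param seed root seed; each stage derives its own via [stageSeed()].
#' @param kGenes,kSamples cluster counts for discovery.
#' @param nBoot,itemFraction consensus resampling scheme.
#' @param cohorts optional named list of [CohortExperiment-class] objects
#'   replacing simulation: all but `validationCohort` are treated as
#'   discovery cohorts.
#' @param validationCohort name of the held-out cohort within `cohorts`
#'   (default `"validation"`); `NULL` for none.
#' @return the manifest, invisibly (list: `config`, `seed`, `stages`,
#'   `files` with md5 checksums, `summary`).
#' @export
runPipeline <- function(config = simulationConfig(), outDir, seed = config@seed,
                        kGenes = 4, kSamples = 5, nBoot = 100,
                        itemFraction = 0.8, cohorts = NULL,
                        validationCohort = "validation") {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(seed = seed, stages = list(), files = list(),
                     version = as.character(utils::packageVersion("ImmuneSubtypes")))
    addFile <- function(path) {
        manifest$files[[basename(path)]] <<-
            unname(tools::md5sum(path))
        path
    }
    stageLog <- function(stage, ...) {
        message(sprintf("[%s] %s", stage, sprintf(...)))
        manifest$stages[[stage]] <<- c(manifest$stages[[stage]], sprintf(...))
    }

    ## stage 1: simulate (or accept user cohorts)
    if (is.null(cohorts)) {
        cfg <- config
        cfg@seed <- as.integer(stageSeed(seed, "simulate"))
        cohorts <- list(
            discoveryA = simulateCohort(cfg, "discoveryA"),
            discoveryB = simulateValidationCohort(cfg, "discoveryB",
                                                  batchShift = 1),
            validation = simulateValidationCohort(cfg, "validation",
                                                  batchShift = 2))
        manifest$config <- list(
            nModules = cfg@nModules, genesPerModule = cfg@genesPerModule,
            nNoiseGenes = cfg@nNoiseGenes,
            subtypeSizes = cfg@subtypeSizes, noiseSd = cfg@noiseSd,
            logHazardBySubtype = cfg@logHazardBySubtype, seed = seed)
    }
    for (nm in names(cohorts))
        addFile(writeExpressionTSV(exprs(cohorts[[nm]]),
                                   file.path(outDir, paste0(nm, "_exprs.tsv"))))
    hasSurvival <- all(vapply(cohorts, function(ce)
        all(c("osTime", "osEvent") %in%
            colnames(SummarizedExperiment::colData(ce))), TRUE))
    if (hasSurvival) {
        clin <- do.call(rbind, lapply(cohorts, survivalData))
        rownames(clin) <- clin$sample
        addFile(writeTableTSV(clin, file.path(outDir, "clinical.tsv")))
    }
    stageLog("simulate", "%d cohort(s): %s", length(cohorts),
             paste(names(cohorts), collapse = ", "))

    discNames <- setdiff(names(cohorts), validationCohort)
    valCE <- if (!is.null(validationCohort) &&
                 validationCohort %in% names(cohorts))
        cohorts[[validationCohort]] else NULL

    ## stage 2: preprocess (curate, merge all cohorts, batch-correct,
    ## standardise once so discovery and validation share one gene scale)
    genes <- suppressMessages(
        curateGenes(cohorts, Reduce(intersect, lapply(cohorts, rownames))))
    merged <- mergeCohorts(cohorts, genes)
    corrected <- combatAdjust(merged)
    standardized <- standardizeGenes(corrected)
    addFile(writeExpressionTSV(exprs(standardized),
                               file.path(outDir, "merged_standardized.tsv")))
    stageLog("preprocess", "%d genes x %d samples after merge+ComBat",
             nrow(standardized), ncol(standardized))

    discIdx <- cohortOf(standardized) %in% discNames
    # gene clustering needs genes centred/scaled over exactly the columns
    # being clustered, so the discovery block is standardised on its own;
    # activities use the shared standardisation so both cohorts stay on one
    # scale for transfer
    discSE <- standardizeGenes(corrected[, discIdx])
    discActSE <- standardized[, discIdx]
    valSE <- if (!is.null(valCE)) standardized[, !discIdx] else NULL

    ## stage 3: discover modules and subtypes on the discovery cohorts
    disc <- discoverSubtypes(discSE, kGenes = kGenes, kSamples = kSamples,
                             nBoot = nBoot, itemFraction = itemFraction,
                             seed = stageSeed(seed, "discover"))
    addFile(writeTableTSV(
        data.frame(gene = names(moduleOf(disc$modules)),
                   module = paste0("GM", moduleOf(disc$modules))),
        file.path(outDir, "modules.tsv")))
    addFile(writeTableTSV(
        data.frame(sample = names(subtypeOf(disc$subtypes)),
                   subtype = as.character(subtypeOf(disc$subtypes)),
                   provenance = provenance(disc$subtypes)),
        file.path(outDir, "subtypes_discovery.tsv")))
    stageLog("discover", "modules sized %s; subtypes sized %s",
             paste(tabulate(moduleOf(disc$modules)), collapse = "/"),
             paste(as.integer(table(subtypeOf(disc$subtypes))), collapse = "/"))

    ## stage 4: activities, centroids, transfer to validation
    discAct <- moduleActivity(discActSE, disc$modules)
    centModel <- subtypeCentroids(discAct, disc$subtypes,
                                  sourceCohort = paste(discNames, collapse = "+"))
    addFile(writeTableTSV(
        data.frame(subtype = rownames(centroids(centModel)),
                   centroids(centModel)),
        file.path(outDir, "centroids.tsv")))
    transferred <- NULL
    if (!is.null(valSE)) {
        valAct <- moduleActivity(valSE, disc$modules)
        transferred <- assignByCentroid(valAct, centModel)
        matched <- clusterThenMatch(valAct, centModel,
                                    k = min(4, ncol(valAct)))
        addFile(writeTableTSV(
            data.frame(sample = names(subtypeOf(transferred)),
                       centroid = as.character(subtypeOf(transferred)),
                       clusterMatch = as.character(subtypeOf(matched))),
            file.path(outDir, "subtypes_validation.tsv")))
        stageLog("transfer", "centroid vs cluster-match agreement %.1f%%",
                 100 * mean(as.character(subtypeOf(transferred)) ==
                            as.character(subtypeOf(matched))))
    }

    ## stage 5: classifier (classes need >= 2 samples to be learnable)
    discLabAll <- subtypeOf(disc$subtypes)
    fitOK <- as.character(discLabAll) %in%
        names(which(table(discLabAll) >= 2))
    model <- fitMultinomial(discAct[, fitOK, drop = FALSE],
                            disc$subtypes,
                            reference = names(which.max(table(
                                droplevels(discLabAll[fitOK])))))
    modelJSON <- file.path(outDir, "classifier.json")
    jsonlite::write_json(list(
        classIds = model@classIds, featureIds = model@featureIds,
        coefficients = model@coefficients, center = model@center,
        scale = model@scale, ridge = model@ridge), modelJSON,
        auto_unbox = TRUE, digits = NA)
    addFile(modelJSON)
    evalRes <- NULL
    if (!is.null(valSE)) {
        proba <- predictProba(model, valAct)
        # reference labels are the centroid-transferred ones: they live in
        # the same discovered label space as the classifier's classes
        yRef <- as.character(subtypeOf(transferred))
        ok <- !is.na(yRef)
        evalRes <- evaluateOvr(yRef[ok], proba[ok, , drop = FALSE])
        addFile(writeTableTSV(evalRes$perClass,
                              file.path(outDir, "classifier_eval.tsv")))
        stageLog("classify", "macro AUROC %.3f, macro AUPRC %.3f",
                 evalRes$macroAUROC, evalRes$macroAUPRC)
    } else stageLog("classify", "model fitted (no validation cohort)")

    ## stage 6: survival
    survReport <- NULL
    if (hasSurvival) {
        discClin <- clin[colnames(discSE), ]
        survReport <- subtypeSurvivalReport(
            discClin, disc$subtypes, adjust = "cohort",
            baselines = list(cohort = discNames[1]))
        addFile(writeTableTSV(survReport$table,
                              file.path(outDir, "survival_summary.tsv")))
        if (!is.null(survReport$cox))
            addFile(writeTableTSV(resultTable(survReport$cox),
                                  file.path(outDir, "cox_table.tsv")))
        stageLog("survival", "overall log-rank p = %.4g",
                 if (is.null(survReport$logrank)) NA else survReport$logrank$p)
    } else stageLog("survival", "skipped (no survival columns)")

    ## stage 7: compare (module activity across subtypes, response strata)
    compareRows <- list()
    for (m in rownames(discAct)) {
        kw <- kruskalWallis(discAct[m, ], subtypeOf(disc$subtypes))
        compareRows[[m]] <- data.frame(feature = m, test = kw$test,
                                       statistic = kw$statistic, p = kw$p)
    }
    compareTab <- do.call(rbind, compareRows)
    addFile(writeTableTSV(compareTab, file.path(outDir, "compare.tsv")))
    responseRes <- NULL
    if (hasSurvival && "response" %in% colnames(clin)) {
        discLab <- subtypeOf(disc$subtypes)
        pairLevels <- intersect(c("IS2", "IS4"), levels(discLab))
        if (length(pairLevels) == 2L)
            responseRes <- withCallingHandlers(
                responseStratifiedSurvival(discClin, disc$subtypes),
                warning = function(w) invokeRestart("muffleWarning"))
    }
    stageLog("compare", "%d module-activity tests", nrow(compareTab))

    manifest$summary <- list(
        nGenes = nrow(standardized), nSamples = ncol(standardized),
        moduleSizes = tabulate(moduleOf(disc$modules)),
        subtypeSizes = as.list(table(subtypeOf(disc$subtypes))),
        macroAUROC = if (!is.null(evalRes)) evalRes$macroAUROC else NULL,
        logrankP = if (!is.null(survReport) && !is.null(survReport$logrank))
            survReport$logrank$p else NULL)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(c(manifest, list(
        discovery = disc, centroids = centModel, transferred = transferred,
        model = model, evaluation = evalRes, survivalReport = survReport,
        response = responseRes)))
}
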