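#' @include AllClasses.R utils.R
NULL

#' @importFrom survival Surv coxph survfit survdiff
NULL

checkSurvival <- function(time, event) {
    if (any(!is.finite(time)) || any(time <= 0))
        stop("times must be positive and finite")
    if (!all(event %in% c(0, 1))) stop("event must be 0/1")
}

#' Kaplan-Meier product-limit curves
#'
#' Product-limit estimator over distinct event times; subjects censored
#' exactly at an event time are counted at risk for that time (the standard
#' convention). Computed through [survival::survfit()].
#'
#' @param time positive follow-up times (months).
#' @param event 0 = censored, 1 = event.
#' @param group optional group labels; one curve per group.
#' @return a single [KMCurve-class], or a named list of them when `group`
#'   is given. A group with no events yields a flat curve flagged
#'   `allCensored`.
#' @export
kmEstimate <- function(time, event, group = NULL) {
    checkSurvival(time, event)
    if (is.null(group)) group <- rep("all", length(time))
    group <- as.character(group)
    curves <- lapply(split(seq_along(time), group), function(idx) {
        fit <- survival::survfit(
            survival::Surv(time[idx], event[idx]) ~ 1, conf.type = "none")
        keep <- fit$n.event > 0
        new("KMCurve",
            time = fit$time[keep], survival = fit$surv[keep],
            nRisk = fit$n.risk[keep], nEvent = fit$n.event[keep],
            group = group[idx][1], allCensored = !any(event[idx] == 1))
    })
    if (length(curves) == 1L) curves[[1]] else curves
}

#' K-group log-rank test
#'
#' Standard unweighted log-rank: observed minus expected events per group
#' under the hypergeometric model, chi-square with k-1 df, through
#' [survival::survdiff()].
#'
#' @inheritParams kmEstimate
#' @param group group labels, at least two groups.
#' @return list: `statistic`, `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
    checkSurvival(time, event)
    group <- factor(group)
    if (nlevels(droplevels(group)) < 2L)
        stop("log-rank needs at least two groups")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    df <- length(sd$n) - 1L
    list(statistic = unname(sd$chisq), df = df,
         p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with explicit baselines
#'
#' Partial-likelihood fit (Efron tie handling by default) of survival on a
#' set of covariates, through [survival::coxph()]. Categorical covariates
#' must name their baseline level explicitly — the analyses this package
#' reproduces switch baselines between runs (worst-prognosis subtype for
#' the subtype variable, a declared stage for stage), so none is defaulted
#' silently. Levels with no events and a monotone likelihood are reported
#' with an `unstable` flag.
#'
#' @param data data.frame with `time`, `event` and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param baselines named list/character: baseline level for every
#'   categorical covariate.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return a [CoxFit-class]; `resultTable()` has one row per covariate
#'   level with logHR, SE, HR, 95% Wald CI and p.
#' @export
coxFit <- function(data, covariates, baselines = list(),
                   ties = c("efron", "breslow")) {
    ties <- match.arg(ties)
    checkSurvival(data$time, data$event)
    if (sum(data$event) < 1) stop("at least one event is required")
    df <- data
    for (v in covariates) {
        if (!v %in% colnames(df)) stop("missing covariate: ", v)
        col <- df[[v]]
        if (is.character(col) || is.factor(col)) {
            base <- baselines[[v]]
            if (is.null(base))
                stop(sprintf("categorical covariate '%s' needs an explicit baseline",
                             v))
            col <- factor(as.character(col))
            if (!base %in% levels(col))
                stop(sprintf("baseline '%s' not a level of '%s'", base, v))
            df[[v]] <- stats::relevel(col, ref = base)
        } else if (length(unique(col)) < 2L) {
            stop(sprintf("covariate '%s' is constant", v))
        }
    }
    fml <- stats::as.formula(paste(
        "survival::Surv(time, event) ~",
        paste(sprintf("`%s`", covariates), collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = ties)
    sm <- summary(fit)
    co <- sm$coefficients
    unstable <- !is.finite(co[, "se(coef)"]) | co[, "se(coef)"] > 100
    if (any(unstable))
        warning("monotone likelihood suspected for: ",
                paste(rownames(co)[unstable], collapse = ", "))
    tab <- data.frame(
        term = gsub("`", "", rownames(co)),
        logHR = unname(co[, "coef"]),
        se = unname(co[, "se(coef)"]),
        HR = unname(exp(co[, "coef"])),
        ciLower = unname(exp(co[, "coef"] - 1.96 * co[, "se(coef)"])),
        ciUpper = unname(exp(co[, "coef"] + 1.96 * co[, "se(coef)"])),
        p = unname(co[, "Pr(>|z|)"]),
        unstable = unname(unstable))
    new("CoxFit", table = tab, ties = ties,
        n = as.integer(sm$n), nEvents = as.integer(sm$nevent), fit = fit)
}

#' Subtype-vs-survival report
#'
#' Assembles the package's standard outcome analysis for a labelled cohort:
#' per-subtype KM curves, the overall k-group log-rank test, a pairwise
#' log-rank between a designated subtype pair (by default the
#' best/worst-prognosis pair of the study design, IS2 vs IS4, when
#' present), and a Cox model of subtype plus adjustment covariates with the
#' declared baselines.
#'
#' @param surv data.frame with `time`, `event` and any adjustment columns
#'   (`cohort`, `stage`, `age`, ...), rownames or `sample` column matching
#'   the labels.
#' @param labels a [SubtypeLabels-class] (or named factor).
#' @param adjust extra covariate names for the Cox model.
#' @param baselines named list of baseline levels; must include `subtype`
#'   (default `"IS4"` when present) and one per categorical adjustment.
#' @param pair the two subtypes compared head-to-head (default
#'   `c("IS2", "IS4")` when present).
#' @return list: `km` (per-subtype [KMCurve-class]), `logrank`,
#'   `pairwiseLogrank` (or NULL), `cox` ([CoxFit-class] or NULL when only
#'   one subtype is present), `table` (tidy summary rows).
#' @export
subtypeSurvivalReport <- function(surv, labels, adjust = character(0),
                                  baselines = list(), pair = NULL) {
    lab <- if (is(labels, "SubtypeLabels")) subtypeOf(labels) else labels
    ids <- if ("sample" %in% colnames(surv)) surv$sample else rownames(surv)
    if (!all(ids %in% names(lab))) stop("labels and survival table share no ids")
    lab <- droplevels(factor(as.character(lab[ids]),
                             levels = levels(factor(lab))))
    df <- data.frame(time = surv$time, event = surv$event,
                     subtype = lab, row.names = NULL)
    for (v in adjust) df[[v]] <- surv[[v]]

    km <- kmEstimate(df$time, df$event, df$subtype)
    if (is(km, "KMCurve")) km <- stats::setNames(list(km), levels(lab)[1])

    single <- nlevels(lab) < 2L
    lr <- if (single) NULL else logrankTest(df$time, df$event, df$subtype)
    if (single) message("single subtype present: log-rank and Cox skipped")

    pair <- pair %||% intersect(c("IS2", "IS4"), levels(lab))
    pairLr <- NULL
    if (!single && length(pair) == 2L && all(pair %in% levels(lab))) {
        sel <- df$subtype %in% pair
        pairLr <- logrankTest(df$time[sel], df$event[sel],
                              droplevels(df$subtype[sel]))
    }

    cox <- NULL
    if (!single) {
        bl <- baselines
        if (is.null(bl$subtype))
            bl$subtype <- if ("IS4" %in% levels(lab)) "IS4" else levels(lab)[1]
        cox <- coxFit(df, covariates = c("subtype", adjust), baselines = bl)
    }

    tab <- data.frame(
        item = c("n", "events", "logrank.chisq", "logrank.p",
                 if (!is.null(pairLr)) c("pair.logrank.chisq", "pair.logrank.p")),
        value = c(nrow(df), sum(df$event),
                  if (is.null(lr)) NA else lr$statistic,
                  if (is.null(lr)) NA else lr$p,
                  if (!is.null(pairLr)) c(pairLr$statistic, pairLr$p)))
    list(km = km, logrank = lr, pairwiseLogrank = pairLr, cox = cox,
         table = tab)
}
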