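#' @include AllClasses.R utils.R survival.R
NULL

#' Kruskal-Wallis rank test across subtypes
#'
#' Tie-corrected H statistic with a chi-square reference on k-1 df, via
#' [stats::kruskal.test()].
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list: `test`, `statistic`, `df`, `p`.
#' @export
kruskalWallis <- function(values, groups) {
    groups <- factor(groups)
    if (nlevels(droplevels(groups)) < 2L)
        stop("Kruskal-Wallis needs at least two groups")
    if (length(unique(values)) == 1L)  # fully tied: H defined as 0
        return(list(test = "kruskal-wallis", statistic = 0,
                    df = nlevels(droplevels(groups)) - 1L, p = 1))
    kt <- stats::kruskal.test(values, groups)
    list(test = "kruskal-wallis", statistic = unname(kt$statistic),
         df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's post hoc test with Bonferroni adjustment
#'
#' Pairwise z statistics from pooled midranks with the usual tie
#' correction:
#' `z = (rbar_i - rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups; two-sided p, Bonferroni
#' multiplied by the number of pairs and capped at 1.
#'
#' @inheritParams kruskalWallis
#' @param adjust only `"bonferroni"` (the study's adjustment) or `"none"`.
#' @return data.frame: `group1`, `group2`, `z`, `p`, `pAdjusted`.
#' @export
dunnPosthoc <- function(values, groups, adjust = c("bonferroni", "none")) {
    adjust <- match.arg(adjust)
    groups <- droplevels(factor(groups))
    if (nlevels(groups) < 2L) stop("need at least two groups")
    if (any(table(groups) == 0)) stop("empty group")
    N <- length(values)
    r <- rank(values)
    rbar <- tapply(r, groups, mean)
    n <- tapply(r, groups, length)
    ties <- table(values)
    Tcorr <- sum(ties^3 - ties)
    varTerm <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
    levs <- levels(groups)
    pairs <- utils::combn(levs, 2)
    out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      z = NA_real_, p = NA_real_)
    for (i in seq_len(ncol(pairs))) {
        a <- pairs[1, i]; b <- pairs[2, i]
        se <- sqrt(varTerm * (1 / n[[a]] + 1 / n[[b]]))
        z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
        out$z[i] <- z
        out$p[i] <- 2 * stats::pnorm(-abs(z))
    }
    out$pAdjusted <- if (adjust == "bonferroni")
        pmin(1, out$p * ncol(pairs)) else out$p
    out
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p by enumeration when the pooled sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie-corrected
#' variance and continuity correction. Via [stats::wilcox.test()].
#'
#' @param x,y the two groups (numeric, non-empty).
#' @param alternative as in [stats::wilcox.test()].
#' @return list: `U`, `p`, `exact`.
#' @export
rankSumTest <- function(x, y, alternative = c("two.sided", "less", "greater")) {
    alternative <- match.arg(alternative)
    if (!length(x) || !length(y)) stop("both groups must be non-empty")
    hasTies <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) + length(y) <= 12) && !hasTies
    wt <- suppressWarnings(stats::wilcox.test(
        x, y, alternative = alternative, exact = exact, correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Association test for a contingency table
#'
#' Fisher's exact test (two-sided by the probability-mass rule) or the
#' Pearson chi-square test without continuity correction (flag available).
#' `method = "auto"` follows the usual rule: Fisher for a 2x2 table with
#' any expected count below 5, chi-square otherwise.
#'
#' @param tab matrix of non-negative integer counts.
#' @param method `"fisher"`, `"chisq"`, or `"auto"`.
#' @param correct apply Yates continuity correction in the chi-square
#'   branch (default FALSE).
#' @return list: `method`, `p`, and `statistic`/`df` (chi-square) or
#'   `oddsRatio` (2x2 Fisher). A table with a zero margin returns p = 1
#'   with a warning.
#' @export
countAssociation <- function(tab, method = c("auto", "fisher", "chisq"),
                             correct = FALSE) {
    method <- match.arg(method)
    tab <- as.matrix(tab)
    if (any(tab < 0) || any(tab != round(tab)))
        stop("counts must be non-negative integers")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning("zero row/column margin: association undefined, p = 1")
        return(list(method = "degenerate", p = 1))
    }
    if (method == "auto") {
        expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        method <- if (all(dim(tab) == c(2L, 2L)) && any(expd < 5))
            "fisher" else "chisq"
    }
    if (method == "fisher") {
        ft <- stats::fisher.test(tab)
        list(method = "fisher", p = ft$p.value,
             oddsRatio = if (all(dim(tab) == c(2L, 2L)))
                 unname(ft$estimate) else NA_real_)
    } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
        list(method = "chisq", statistic = unname(ct$statistic),
             df = unname(ct$parameter), p = ct$p.value)
    }
}

#' Stromal fraction from tumor purity
#'
#' The non-tumor cellular component: `1 - purity`.
#'
#' @param purity numeric in \[0,1\] (vectorised).
#' @return `1 - purity`.
#' @export
stromalFraction <- function(purity) {
    if (any(!is.finite(purity)) || any(purity < 0 | purity > 1))
        stop("purity must lie in [0,1]")
    1 - purity
}

#' Absolute immune-cell proportions
#'
#' Scales relative (deconvolution) cell-type fractions by the sample's
#' leukocyte fraction, elementwise, so the output sums to
#' `leukocyteFraction * sum(relative)`.
#'
#' @param relative per-cell-type relative fractions in \[0,1\].
#' @param leukocyteFraction scalar (or per-entry) leukocyte fraction in
#'   \[0,1\].
#' @return absolute proportions, same shape as `relative`.
#' @export
absoluteProportions <- function(relative, leukocyteFraction) {
    if (any(relative < 0 | relative > 1) ||
        any(leukocyteFraction < 0 | leukocyteFraction > 1))
        stop("fractions must lie in [0,1]")
    relative * leukocyteFraction
}

#' Survival by subtype within response strata
#'
#' Within each treatment-response stratum, compares the designated subtype
#' pair by KM + log-rank; also tests subtype-by-response association with a
#' chi-square on the count table. Strata containing fewer than two
#' subtypes are skipped with a warning.
#'
#' @param surv data.frame with `time`, `event` and a `response` column.
#' @param labels a [SubtypeLabels-class] or named factor.
#' @param pair the two subtypes compared (default `c("IS2","IS4")` when
#'   present).
#' @return list: `strata` (per response level: `km`, `logrank` or NULL,
#'   `skipped`), `association` (chi-square of subtype x response counts),
#'   `counts` (the table itself).
#' @export
responseStratifiedSurvival <- function(surv, labels, pair = NULL) {
    if (!"response" %in% colnames(surv)) stop("response column required")
    lab <- if (is(labels, "SubtypeLabels")) subtypeOf(labels) else labels
    ids <- if ("sample" %in% colnames(surv)) surv$sample else rownames(surv)
    lab <- droplevels(factor(as.character(lab[ids])))
    pair <- pair %||% intersect(c("IS2", "IS4"), levels(lab))
    if (length(pair) != 2L) stop("a subtype pair is required")

    counts <- table(subtype = lab, response = surv$response)
    assoc <- countAssociation(counts[pair, , drop = FALSE], method = "chisq")

    strata <- lapply(split(seq_len(nrow(surv)), surv$response), function(idx) {
        sel <- idx[lab[idx] %in% pair]
        sub <- droplevels(lab[sel])
        if (nlevels(sub) < 2L) {
            warning("response stratum with fewer than two subtypes skipped")
            return(list(km = NULL, logrank = NULL, skipped = TRUE))
        }
        list(km = kmEstimate(surv$time[sel], surv$event[sel], sub),
             logrank = logrankTest(surv$time[sel], surv$event[sel], sub),
             skipped = FALSE)
    })
    list(strata = strata, association = assoc, counts = counts)
}
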