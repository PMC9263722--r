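# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately naive re-derivations (enumeration, brute force),
# never calls into the code paths they check.

# A reduced configuration for fast unit tests; the acceptance tests use the
# package defaults.
smallConfig <- function(...) {
    args <- list(...)
    defaults <- list(genesPerModule = 15, nNoiseGenes = 60,
                     subtypeSizes = rep(20L, 5), seed = 42L)
    do.call(simulationConfig, utils::modifyList(defaults, args))
}

# Co-membership indicator matrix of a hard clustering.
coMembership <- function(labels) {
    outer(labels, labels, "==") * 1
}

# Independent Efron partial log-likelihood for a single covariate.
# Implemented straight from the definition: per distinct event time, the
# tied events' risk-set sums are down-weighted progressively.
efronLogPL <- function(beta, time, event, x) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
        D <- which(time == t & event == 1)
        R <- which(time >= t)
        d <- length(D)
        sumR <- sum(exp(beta * x[R]))
        sumD <- sum(exp(beta * x[D]))
        ll <- ll + beta * sum(x[D])
        for (l in seq_len(d) - 1)
            ll <- ll - log(sumR - (l / d) * sumD)
    }
    ll
}

# Independent k-group log-rank chi-square from the O-E / hypergeometric-V
# table (2-group form).
logrankChisqOracle <- function(time, event, group) {
    g <- as.integer(factor(group))
    stopifnot(max(g) == 2)
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(time[event == 1]))) {
        atRisk <- time >= t
        n <- sum(atRisk)
        n1 <- sum(atRisk & g == 1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & g == 1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration
# (probability-mass-at-most-observed rule).
fisherOracle <- function(tab) {
    a <- tab[1, 1]
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Empirical per-subtype module activity of a simulated cohort, from truth.
truthActivity <- function(ce) {
    moduleActivity(exprs(ce), moduleOf(trueModules(ce)))
}
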