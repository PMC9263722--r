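#' @include AllClasses.R utils.R
NULL

# Penalised multinomial negative log-likelihood and gradient.
# beta: (K-1) x (p+1) with column 1 the intercept; reference class has
# implicit zero coefficients. Ridge applies to non-intercept weights only.
multinomNLL <- function(betaVec, X1, Y, ridge) {
    K1 <- ncol(Y) - 1L
    beta <- matrix(betaVec, K1, ncol(X1))
    eta <- cbind(0, X1 %*% t(beta))            # n x K, reference first
    etaMax <- apply(eta, 1, max)
    logZ <- etaMax + log(rowSums(exp(eta - etaMax)))
    nll <- -sum(rowSums(Y * eta) - logZ)
    pen <- beta
    pen[, 1] <- 0
    nll + 0.5 * ridge * sum(pen^2)
}

multinomGrad <- function(betaVec, X1, Y, ridge) {
    K1 <- ncol(Y) - 1L
    beta <- matrix(betaVec, K1, ncol(X1))
    eta <- cbind(0, X1 %*% t(beta))
    etaMax <- apply(eta, 1, max)
    P <- exp(eta - etaMax)
    P <- P / rowSums(P)
    D <- P[, -1, drop = FALSE] - Y[, -1, drop = FALSE]  # n x (K-1)
    G <- t(D) %*% X1
    pen <- beta
    pen[, 1] <- 0
    as.vector(G + ridge * pen)
}

#' Fit a multinomial logistic subtype classifier on module activities
#'
#' Maximises the softmax log-likelihood with the reference class fixed at
#' zero, plus an optional ridge penalty on non-intercept weights (default
#' `1e-4`, which keeps coefficients finite on separable data). Features are
#' standardised internally and the transform stored with the model.
#' Optimisation is BFGS with analytic gradient; convergence is declared
#' when the gradient sup-norm falls below `1e-6` (up to 500 iterations),
#' otherwise the model is returned with a warning and `converged = FALSE`.
#'
#' @param activity module-by-sample matrix ([moduleActivity()]).
#' @param labels a [SubtypeLabels-class] or named factor over the samples.
#' @param reference reference class (default: first level).
#' @param ridge ridge penalty on non-intercept weights (>= 0).
#' @param standardize standardise features internally (default TRUE).
#' @return a [MultinomialModel-class].
#' @export
fitMultinomial <- function(activity, labels, reference = NULL, ridge = 1e-4,
                           standardize = TRUE) {
    lab <- if (is(labels, "SubtypeLabels")) subtypeOf(labels) else labels
    if (!is.null(names(lab))) lab <- lab[colnames(activity)]
    lab <- droplevels(factor(as.character(lab),
                             levels = if (is.factor(lab)) levels(lab) else NULL))
    if (length(lab) != ncol(activity) || any(is.na(lab)))
        stop("labels must cover every sample")
    if (nlevels(lab) < 2L) stop("at least two classes are required")
    if (any(table(lab) < 2L)) stop("every class needs at least 2 samples")
    if (ridge < 0) stop("ridge must be non-negative")

    reference <- reference %||% levels(lab)[1]
    if (!reference %in% levels(lab)) stop("reference class not in labels")
    classIds <- c(reference, setdiff(levels(lab), reference))
    lab <- factor(lab, levels = classIds)

    X <- t(activity)                            # n x p
    keep <- apply(X, 2, stats::sd) > 0
    if (!all(keep)) {
        warning("dropping ", sum(!keep), " zero-variance feature(s)")
        X <- X[, keep, drop = FALSE]
    }
    p <- ncol(X)
    if (standardize && p > 0) {
        ctr <- colMeans(X)
        scl <- apply(X, 2, stats::sd)
        X <- scale(X, ctr, scl)
    } else {
        ctr <- rep(0, p); scl <- rep(1, p)
    }
    n <- nrow(X)
    K <- nlevels(lab)
    Y <- matrix(0, n, K)
    Y[cbind(seq_len(n), as.integer(lab))] <- 1
    X1 <- cbind(1, X)

    beta0 <- rep(0, (K - 1L) * (p + 1L))
    opt <- stats::optim(beta0, multinomNLL, multinomGrad, X1 = X1, Y = Y,
                        ridge = ridge, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    gnorm <- max(abs(multinomGrad(opt$par, X1, Y, ridge)))
    if (gnorm >= 1e-6) {
        # polish with a few more restarts before giving up
        for (i in 1:3) {
            opt <- stats::optim(opt$par, multinomNLL, multinomGrad, X1 = X1,
                                Y = Y, ridge = ridge, method = "BFGS",
                                control = list(maxit = 500, reltol = 1e-14))
            gnorm <- max(abs(multinomGrad(opt$par, X1, Y, ridge)))
            if (gnorm < 1e-6) break
        }
    }
    converged <- gnorm < 1e-6
    if (!converged)
        warning(sprintf("fit did not reach gradient tolerance (sup-norm %.2e)",
                        gnorm))
    coefs <- matrix(opt$par, K - 1L, p + 1L,
                    dimnames = list(classIds[-1],
                                    c("(Intercept)", colnames(X))))
    new("MultinomialModel", classIds = classIds,
        featureIds = colnames(X) %||% character(0),
        coefficients = coefs,
        center = stats::setNames(ctr, colnames(X)),
        scale = stats::setNames(scl, colnames(X)),
        ridge = ridge, converged = converged,
        meta = list(n = n, classCounts = as.list(table(lab))))
}

#' Class probabilities from a fitted multinomial model
#'
#' @param model a [MultinomialModel-class].
#' @param activity module-by-sample matrix with the training modules.
#' @return sample-by-class probability matrix; rows sum to 1.
#' @export
predictProba <- function(model, activity) {
    feats <- model@featureIds
    if (!all(feats %in% rownames(activity)))
        stop("activity is missing trained module(s): ",
             paste(setdiff(feats, rownames(activity)), collapse = ", "))
    X <- t(activity[feats, , drop = FALSE])
    X <- scale(X, model@center, model@scale)
    eta <- cbind(0, cbind(1, X) %*% t(model@coefficients))
    etaMax <- apply(eta, 1, max)
    P <- exp(eta - etaMax)
    P <- P / rowSums(P)
    dimnames(P) <- list(colnames(activity), model@classIds)
    P
}

#' One-vs-rest ROC / precision-recall evaluation
#'
#' Per class, AUROC is the Mann-Whitney statistic `U / (n+ * n-)` on that
#' class's probability column (ties counted 1/2); AUPRC is the step
#' interpolation of the precision-recall curve (precision at each distinct
#' score threshold, weighted by the recall gained there). Macro averages
#' are unweighted means over classes present in `yTrue`; absent classes are
#' reported as `NA`, not 0.
#'
#' @param yTrue true labels (factor/character), one per row of `proba`.
#' @param proba sample-by-class probability (or score) matrix with class
#'   column names.
#' @return list: `perClass` (data.frame class, n, auroc, auprc),
#'   `macroAUROC`, `macroAUPRC`, `confusion` (argmax confusion matrix,
#'   true in rows).
#' @export
evaluateOvr <- function(yTrue, proba) {
    yTrue <- as.character(yTrue)
    stopifnot(length(yTrue) == nrow(proba))
    classes <- colnames(proba)
    perClass <- data.frame(class = classes, n = NA_integer_,
                           auroc = NA_real_, auprc = NA_real_)
    for (i in seq_along(classes)) {
        pos <- yTrue == classes[i]
        perClass$n[i] <- sum(pos)
        if (!any(pos) || all(pos)) next
        s <- proba[, i]
        perClass$auroc[i] <- aurocMW(s, pos)
        perClass$auprc[i] <- auprcStep(s, pos)
    }
    pred <- classes[max.col(proba, ties.method = "first")]
    confusion <- table(true = factor(yTrue, levels = classes),
                       predicted = factor(pred, levels = classes))
    list(perClass = perClass,
         macroAUROC = mean(perClass$auroc, na.rm = TRUE),
         macroAUPRC = mean(perClass$auprc, na.rm = TRUE),
         confusion = confusion)
}

# AUROC as normalized Mann-Whitney U with midrank ties.
aurocMW <- function(scores, positive) {
    r <- rank(scores)
    nPos <- sum(positive)
    nNeg <- sum(!positive)
    (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Step-interpolated area under the precision-recall curve: walk thresholds
# from the highest distinct score down; add precision * delta-recall.
auprcStep <- function(scores, positive) {
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    y <- positive[ord]
    nPos <- sum(y)
    cumTP <- cumsum(y)
    cumP <- seq_along(y)
    last <- !duplicated(s, fromLast = TRUE)    # last index of each tie block
    tp <- cumTP[last]
    prec <- tp / cumP[last]
    rec <- tp / nPos
    sum(prec * diff(c(0, rec)))
}
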