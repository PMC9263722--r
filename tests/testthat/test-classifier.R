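# Independent negative log-likelihood for a 2-class, 1-feature model with
# ridge on the slope only (the package's penalty definition), used as a
# brute-force oracle.
nll2 <- function(b0, b1, x, y01, ridge) {
    eta <- b0 + b1 * x
    -sum(y01 * eta - log1p(exp(eta))) + 0.5 * ridge * b1^2
}

test_that("intercept-only fits reproduce class frequencies", {
    act <- matrix(5, 1, 12, dimnames = list("GM1", paste0("s", 1:12)))
    lab <- factor(rep(c("IS1", "IS2", "IS4"), times = c(6, 4, 2)))
    names(lab) <- colnames(act)
    expect_warning(m <- fitMultinomial(act, lab), "zero-variance")
    p <- predictProba(m, act)
    expect_equal(unname(p[1, ]), c(6, 4, 2) / 12, tolerance = 1e-6)
})

test_that("fitted coefficients match a brute-force likelihood maximisation", {
    x <- c(-1.2, -0.5, 0.1, 0.4, 1.0, 1.7)
    y <- factor(c("A", "A", "B", "A", "B", "B"))
    act <- matrix(x, 1, 6, dimnames = list("GM1", paste0("s", 1:6)))
    names(y) <- colnames(act)
    ridge <- 1e-2
    m <- fitMultinomial(act, y, reference = "A", ridge = ridge,
                        standardize = FALSE)
    # oracle: dense grid then Nelder-Mead polish on the independent NLL
    grid <- expand.grid(b0 = seq(-4, 4, 0.1), b1 = seq(-1, 8, 0.1))
    gv <- mapply(nll2, grid$b0, grid$b1,
                 MoreArgs = list(x = x, y01 = as.integer(y == "B"),
                                 ridge = ridge))
    start <- as.numeric(grid[which.min(gv), ])
    opt <- optim(start, function(b) nll2(b[1], b[2], x, as.integer(y == "B"),
                                         ridge),
                 control = list(reltol = 1e-14, maxit = 5000))
    expect_lt(max(abs(coefficientsOf(m)["B", ] - opt$par)), 1e-3)
})

test_that("ridge keeps separable problems finite and fully accurate", {
    act <- matrix(c(-3, -2, -1, 1, 2, 3), 1, 6,
                  dimnames = list("GM1", paste0("s", 1:6)))
    y <- factor(rep(c("A", "B"), each = 3))
    names(y) <- colnames(act)
    m <- fitMultinomial(act, y, ridge = 1e-4)
    expect_true(all(is.finite(coefficientsOf(m))))
    p <- predictProba(m, act)
    expect_equal(unname(colnames(p)[max.col(p)]), as.character(y))
})

test_that("predictProba is a proper softmax", {
    m <- new("MultinomialModel", classIds = c("A", "B", "C"),
             featureIds = c("GM1", "GM2"),
             coefficients = matrix(0, 2, 3,
                                   dimnames = list(c("B", "C"), NULL)),
             center = c(0, 0), scale = c(1, 1), ridge = 0,
             converged = TRUE, meta = list())
    act <- matrix(rnorm(10), 2, 5,
                  dimnames = list(c("GM1", "GM2"), paste0("s", 1:5)))
    p <- predictProba(m, act)
    expect_equal(unname(p), matrix(1 / 3, 5, 3))   # all-zero coefficients
    m@coefficients <- matrix(c(0.5, -1, 2, 0.3, -0.7, 1.1), 2, 3)
    p2 <- predictProba(m, act)
    expect_equal(rowSums(p2), setNames(rep(1, 5), colnames(act)),
                 tolerance = 1e-12)
    expect_error(predictProba(m, act[1, , drop = FALSE]), "missing")
})

test_that("training log-loss never exceeds the intercept-only log-loss", {
    cfg <- smallConfig()
    ce <- simulateCohort(cfg, "d")
    act <- truthActivity(ce)
    lab <- subtypeOf(trueSubtypes(ce))
    m <- fitMultinomial(act, lab)
    p <- predictProba(m, act)
    ll <- -mean(log(p[cbind(seq_along(lab), match(lab, colnames(p)))]))
    freq <- as.numeric(table(lab)[as.character(lab)]) / length(lab)
    expect_lte(ll, -mean(log(freq)) + 1e-9)
})

test_that("fit agrees with the reference multinomial implementation", {
    # nnet::multinom with decay 0 maximises the same unpenalised likelihood;
    # on a non-separable instance both should land on the same optimum
    withr::with_seed(5, {
        n <- 60
        x <- matrix(rnorm(2 * n), 2, n,
                    dimnames = list(c("GM1", "GM2"), paste0("s", 1:n)))
        eta <- rbind(0, 1.2 * x[1, ] - 0.5 * x[2, ], -0.8 * x[1, ])
        pr <- t(apply(eta, 2, function(e) exp(e) / sum(exp(e))))
        y <- factor(apply(pr, 1, function(p) sample(c("A", "B", "C"), 1,
                                                    prob = p)),
                    levels = c("A", "B", "C"))
    })
    names(y) <- colnames(x)
    m <- fitMultinomial(x, y, reference = "A", ridge = 0, standardize = FALSE)
    ref <- nnet::multinom(y ~ t(x), trace = FALSE, decay = 0, maxit = 500,
                          reltol = 1e-14)
    expect_equal(unname(coefficientsOf(m)), unname(coef(ref)),
                 tolerance = 1e-3)
})

test_that("one-vs-rest AUROC and AUPRC match pair/step enumeration", {
    y <- c("A", "A", "A", "B", "B", "B", "B", "B")
    scoreA <- c(0.9, 0.8, 0.35, 0.7, 0.3, 0.2, 0.35, 0.1)
    proba <- cbind(A = scoreA, B = 1 - scoreA)
    ev <- evaluateOvr(y, proba)
    # oracle: concordant-pair count with ties at 1/2
    pos <- which(y == "A"); neg <- which(y == "B")
    conc <- 0
    for (i in pos) for (j in neg)
        conc <- conc + (scoreA[i] > scoreA[j]) + 0.5 * (scoreA[i] == scoreA[j])
    expect_equal(ev$perClass$auroc[1], conc / (length(pos) * length(neg)))
    # oracle: walk distinct thresholds, accumulate precision * delta-recall
    thr <- sort(unique(scoreA), decreasing = TRUE)
    rec0 <- 0; ap <- 0
    for (t in thr) {
        sel <- scoreA >= t
        prec <- sum(y[sel] == "A") / sum(sel)
        rec <- sum(y[sel] == "A") / length(pos)
        ap <- ap + prec * (rec - rec0)
        rec0 <- rec
    }
    expect_equal(ev$perClass$auprc[1], ap)
    expect_equal(dim(ev$confusion), c(2L, 2L))
})

test_that("AUROC obeys its boundary and invariance properties", {
    y <- rep(c("A", "B"), each = 4)
    perfect <- cbind(A = c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1),
                     B = 0.5)
    ev <- evaluateOvr(y, perfect)
    expect_equal(ev$perClass$auroc[1], 1)
    expect_equal(ev$perClass$auroc[2], 0.5)   # constant scores: all ties
    # strictly monotone transform leaves AUROC unchanged
    warped <- cbind(A = exp(3 * perfect[, "A"]), B = perfect[, "B"])
    expect_equal(evaluateOvr(y, warped)$perClass$auroc,
                 ev$perClass$auroc)
    # a class absent from the truth is NA, not 0
    ev2 <- evaluateOvr(rep("A", 8), perfect)
    expect_true(is.na(ev2$perClass$auroc[2]))
})
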