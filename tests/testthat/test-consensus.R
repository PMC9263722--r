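# A tiny well-separated dataset: two clouds 100x their internal spread apart.
twoClouds <- function(nPer = 10, sep = 100, seed = 3) {
    withr::with_seed(seed, {
        x <- rbind(matrix(rnorm(nPer * 4, 0, 1), nPer),
                   matrix(rnorm(nPer * 4, sep, 1), nPer))
    })
    rownames(x) <- sprintf("i%02d", seq_len(2 * nPer))
    x
}

test_that("consensus matrix satisfies its defining contracts", {
    x <- twoClouds()
    cr <- consensusCluster(x, k = 2, nBoot = 50, seed = 1)
    cm <- consensus(cr)
    expect_true(all(diag(cm) == 1))
    expect_identical(cm, t(cm))
    expect_true(all(cm >= 0 & cm <= 1))
    # perfect-separation limit: within-cloud 1, between-cloud 0
    expect_true(all(cm[1:10, 1:10] == 1))
    expect_true(all(cm[1:10, 11:20] == 0))
    # the ratio definition holds wherever pairs were sampled
    seen <- cr@coSampleCounts > 0
    expect_equal(cm[seen & upper.tri(cm)],
                 (cr@coClusterCounts / cr@coSampleCounts)[seen & upper.tri(cm)])
    # co-sampling counts concentrate around B * fraction^2
    off <- cr@coSampleCounts[upper.tri(cm)]
    expect_lt(max(abs(off - 50 * 0.8^2)), 4 * sqrt(50 * 0.64 * 0.36) + 2)
})

test_that("full-fraction consensus equals the brute-force co-membership matrix", {
    withr::with_seed(11, x <- matrix(rnorm(6 * 3), 6, 3))
    rownames(x) <- paste0("i", 1:6)
    cr <- consensusCluster(x, k = 2, nBoot = 3, itemFraction = 1)
    # oracle: one full-data average-linkage clustering, recomputed naively
    lab <- stats::cutree(stats::hclust(stats::dist(x), "average"), 2)
    expect_equal(unname(consensus(cr)), coMembership(unname(lab)))
    expect_true(all(consensus(cr) %in% c(0, 1)))
})

test_that("subsampled consensus matches a resample-by-resample oracle", {
    # same seed => same subsample sequence; the oracle repeats the exact
    # resampling protocol but accumulates indicators independently
    withr::with_seed(12, x <- matrix(rnorm(8 * 3), 8, 3))
    rownames(x) <- paste0("i", 1:8)
    n <- 8; B <- 7; frac <- 0.8; m <- ceiling(frac * n)
    suppressWarnings(cr <- consensusCluster(x, k = 2, nBoot = B,
                                            itemFraction = frac, seed = 5))
    num <- matrix(0, n, n); den <- matrix(0, n, n)
    set.seed(5)
    for (b in 1:B) {
        idx <- sample.int(n, m)
        cl <- stats::cutree(stats::hclust(stats::dist(x[idx, ]), "average"), 2)
        den[idx, idx] <- den[idx, idx] + 1
        num[idx, idx] <- num[idx, idx] + coMembership(cl)
    }
    expected <- ifelse(den > 0, num / pmax(den, 1), 0)
    diag(expected) <- 1
    expect_equal(unname(consensus(cr)), expected)
})

test_that("consensus CDF area matches an independent integration", {
    x <- twoClouds()
    cr <- consensusCluster(x, k = 2, nBoot = 20, seed = 2)
    v <- consensus(cr)[upper.tri(consensus(cr))]
    # all-binary consensus: area equals the proportion of zeros
    expect_equal(areaUnderCDF(cr), mean(v == 0), tolerance = 0.011)
    # noisy instance: fine Riemann sum of the empirical CDF as oracle
    withr::with_seed(4, y <- matrix(rnorm(12 * 3), 12, 3))
    rownames(y) <- paste0("i", 1:12)
    cr2 <- consensusCluster(y, k = 3, nBoot = 25, seed = 9)
    v2 <- consensus(cr2)[upper.tri(consensus(cr2))]
    grid <- seq(0, 1, length.out = 20001)
    riemann <- mean(vapply(grid, function(g) mean(v2 <= g), 0))
    expect_equal(areaUnderCDF(cr2), riemann, tolerance = 0.005)
})

test_that("selectK follows the relative delta-area rule", {
    fakeResult <- function(k, area) {
        cm <- diag(3); new("ConsensusResult", k = as.integer(k),
                           consensus = cm, coClusterCounts = cm,
                           coSampleCounts = cm, labels = c(a = 1L, b = 2L, c = 3L),
                           cdfGrid = data.frame(), areaUnderCDF = area,
                           scheme = list())
    }
    flat <- lapply(2:6, fakeResult, area = 0.4)
    expect_equal(selectK(flat)$k, 2L)
    # dominant jump at k = 4
    jump <- Map(fakeResult, 2:6, c(0.30, 0.32, 0.60, 0.615, 0.62))
    expect_equal(selectK(jump)$k, 4L)
    expect_named(selectK(jump)$curve, c("k", "area", "deltaArea"))
    expect_error(selectK(list(fakeResult(2, 1), fakeResult(4, 1))),
                 "consecutive")
})

test_that("cutConsensus recovers blocks and is order/relabel invariant", {
    blocks <- matrix(0, 6, 6)
    blocks[1:3, 1:3] <- 1; blocks[4:6, 4:6] <- 1; diag(blocks) <- 1
    rownames(blocks) <- colnames(blocks) <- paste0("i", 1:6)
    cr <- new("ConsensusResult", k = 2L, consensus = blocks,
              coClusterCounts = blocks, coSampleCounts = blocks + 1,
              labels = integer(0), cdfGrid = data.frame(),
              areaUnderCDF = 0.5, scheme = list())
    lab <- cutConsensus(cr, 2)
    expect_equal(unname(lab), c(1, 1, 1, 2, 2, 2))
    # renumbering is by decreasing size with smallest-member tie-break
    x <- twoClouds(nPer = 6)
    cr1 <- consensusCluster(x, k = 2, nBoot = 30, seed = 1)
    perm <- withr::with_seed(2, sample(nrow(x)))
    cr2 <- consensusCluster(x[perm, ], k = 2, nBoot = 30, seed = 8)
    l1 <- clusterLabels(cr1)[rownames(x)]
    l2 <- clusterLabels(cr2)[rownames(x)]
    expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
    sizes <- tabulate(clusterLabels(cr1))
    expect_true(all(diff(sizes) <= 0))
})

test_that("discovery on planted data recovers modules and subtypes", {
    cfg <- smallConfig(noiseSd = 0.25)
    ce <- simulateCohort(cfg, "d")
    std <- standardizeGenes(ce)
    disc <- discoverSubtypes(std, kGenes = 4, kSamples = 5, nBoot = 40,
                             seed = 3)
    tm <- moduleOf(trueModules(ce)); inMod <- !is.na(tm)
    expect_gte(mclust::adjustedRandIndex(moduleOf(disc$modules)[inMod],
                                         tm[inMod]), 0.9)
    expect_gte(mclust::adjustedRandIndex(
        as.character(subtypeOf(disc$subtypes)),
        as.character(subtypeOf(trueSubtypes(ce)))), 0.9)
    # deterministic under a fixed seed
    disc2 <- discoverSubtypes(std, kGenes = 4, kSamples = 5, nBoot = 40,
                              seed = 3)
    expect_identical(subtypeOf(disc$subtypes), subtypeOf(disc2$subtypes))
})

test_that("recovery degrades as noise grows (non-strict)", {
    ariAt <- function(noise) {
        med <- vapply(1:3, function(s) {
            ce <- simulateCohort(smallConfig(noiseSd = noise, seed = s), "d")
            std <- standardizeGenes(ce)
            cr <- consensusCluster(t(exprs(std)), k = 5, nBoot = 25, seed = s)
            mclust::adjustedRandIndex(clusterLabels(cr),
                                      as.integer(subtypeOf(trueSubtypes(ce))))
        }, 0)
        stats::median(med)
    }
    expect_gte(ariAt(0.3), ariAt(4) - 1e-9)
})

test_that("degenerate consensus inputs are rejected", {
    x <- twoClouds(nPer = 3)
    expect_error(consensusCluster(x, k = 1), "at least 2")
    expect_error(consensusCluster(x, k = 7), "exceeds")
    expect_error(consensusCluster(x, k = 2, itemFraction = 0), "itemFraction")
    expect_error(cutConsensus(consensusCluster(x, k = 2, nBoot = 5), 10),
                 "exceeds")
})
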