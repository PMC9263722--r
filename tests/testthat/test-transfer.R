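# Small deterministic activity fixtures plus planted-truth simulations.

test_that("moduleActivity is the per-module gene mean", {
    x <- matrix(c(1, 3, 10, 2, 4, 20), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
    map <- c(g1 = 1L, g2 = 1L, g3 = 2L)
    act <- moduleActivity(x, map)
    expect_equal(act["GM1", ], c(s1 = 2, s2 = 3))
    # singleton module equals that gene's row
    expect_equal(act["GM2", ], x["g3", ])
    # invariant to gene order within a module
    act2 <- moduleActivity(x[c(3, 2, 1), ], map)
    expect_equal(act, act2[rownames(act), ])
    # linearity in the expression matrix
    y <- x + 2
    expect_equal(moduleActivity((x + y) / 2, map),
                 (act + moduleActivity(y, map)) / 2)
    expect_error(moduleActivity(x[1:2, ], map), "module 2 has no genes")
})

test_that("subtypeCentroids averages activity columns per subtype", {
    act <- matrix(c(1, 2, 3, 5, 7, 11, 13, 17, 19), 3, 3,
                  dimnames = list(paste0("GM", 1:3), c("a", "b", "c")))
    lab <- factor(c(a = "IS1", b = "IS2", c = "IS2"))
    cm <- subtypeCentroids(act, lab)
    expect_equal(centroids(cm)["IS1", ], act[, "a"])
    expect_equal(centroids(cm)["IS2", ], (act[, "b"] + act[, "c"]) / 2)
    expect_error(subtypeCentroids(act, factor(c(a = "IS1", b = "IS1"))),
                 "missing")
})

test_that("zero-noise centroids equal the planted activity pattern", {
    cfg <- smallConfig(noiseSd = 0)
    ce <- simulateCohort(cfg, "d")
    cm <- subtypeCentroids(truthActivity(ce), trueSubtypes(ce))
    expect_equal(centroids(cm), plantedCentroids(ce), tolerance = 1e-12)
    # removing the gene-level base mean leaves exactly the pattern rows
    base <- plantedCentroids(ce) - cfg@activityPattern
    expect_equal(centroids(cm) - base, cfg@activityPattern, tolerance = 1e-12)
})

test_that("assignByCentroid follows Pearson correlation with exclusions", {
    cent <- rbind(IS1 = c(1, 0, 0, 0), IS2 = c(0, 1, 0, 0),
                  IS3 = c(0.2, 0.2, 0.2, 0.2), IS4 = c(0, 0, 1, 0),
                  IS5 = c(0, 0, 0, 1))
    colnames(cent) <- paste0("GM", 1:4)
    model <- new("CentroidModel", centroids = cent, sourceCohort = "disc")
    act <- cbind(s1 = cent["IS2", ],                 # exact centroid
                 s2 = cent["IS4", ] + 10,            # shifted: Pearson-invariant
                 s3 = 3 * cent["IS5", ] + 1,         # affine, positive slope
                 s4 = c(1, 1, 1, 1))                 # zero variance
    rownames(act) <- paste0("GM", 1:4)
    expect_warning(lab <- assignByCentroid(act, model), "zero-variance")
    expect_equal(as.character(subtypeOf(lab))[1:3], c("IS2", "IS4", "IS5"))
    expect_true(is.na(subtypeOf(lab)["s4"]))
    expect_identical(provenance(lab), "centroid")
    # the intermediate subtype is excluded by default ...
    expect_false("IS3" %in% as.character(subtypeOf(lab)))
    # ... but receives low-confidence samples under an ambiguity threshold
    actAmb <- cbind(s1 = c(1, -1, 1, -1) * 0.1 + cent["IS3", ])
    rownames(actAmb) <- paste0("GM", 1:4)
    labAmb <- assignByCentroid(actAmb, model, ambiguityThreshold = 0.999)
    expect_equal(as.character(subtypeOf(labAmb)), "IS3")
    expect_error(assignByCentroid(act[1:2, ], model), "at least 3 modules")
})

test_that("clusterThenMatch matches greedily and honours reuse", {
    cent <- rbind(IS1 = c(10, 0, 0), IS2 = c(0, 10, 0), IS4 = c(0, 0, 10))
    colnames(cent) <- paste0("GM", 1:3)
    model <- new("CentroidModel", centroids = cent, sourceCohort = "disc")
    # two tight clusters, both most similar to IS1's direction
    act <- cbind(a1 = c(10, 0.4, 0.0), a2 = c(10, 0.5, 0.0),
                 b1 = c(9.5, 0.0, 0.4), b2 = c(9.5, 0.0, 0.5))
    rownames(act) <- paste0("GM", 1:3)
    noReuse <- clusterThenMatch(act, model, k = 2, excludeSubtypes = character(0))
    labs <- as.character(subtypeOf(noReuse))
    expect_length(unique(labs), 2)       # one-to-one: second takes next best
    expect_true("IS1" %in% labs)
    reuse <- clusterThenMatch(act, model, k = 2,
                              excludeSubtypes = character(0), allowReuse = TRUE)
    expect_equal(unique(as.character(subtypeOf(reuse))), "IS1")
    expect_error(clusterThenMatch(act, model, k = 9), "exceeds")
})

test_that("both transfer routes recover planted truth on clean data", {
    cfg <- smallConfig(noiseSd = 0)
    ce <- simulateCohort(cfg, "d")
    val <- simulateValidationCohort(cfg, "v", batchShift = 0)
    cm <- subtypeCentroids(truthActivity(ce), trueSubtypes(ce))
    valAct <- truthActivity(val)
    truth <- as.character(subtypeOf(trueSubtypes(val)))
    chr <- truth != "IS3"
    byCent <- as.character(subtypeOf(assignByCentroid(valAct, cm)))
    expect_equal(byCent[chr], truth[chr])
    byClust <- as.character(subtypeOf(clusterThenMatch(valAct, cm, k = 4)))
    expect_equal(byClust[chr], truth[chr])
})

test_that("centroid and cluster-match transfers agree at default noise", {
    cfg <- smallConfig()
    ce <- simulateCohort(cfg, "d")
    val <- simulateValidationCohort(cfg, "v", batchShift = 1)
    merged <- mergeCohorts(list(ce, val), rownames(ce))
    std <- standardizeGenes(combatAdjust(merged))
    isVal <- cohortOf(std) == "v"
    cm <- subtypeCentroids(
        moduleActivity(std[, !isVal], trueModules(ce)),
        trueSubtypes(ce))
    valAct <- moduleActivity(std[, isVal], trueModules(ce))
    a <- as.character(subtypeOf(assignByCentroid(valAct, cm)))
    b <- as.character(subtypeOf(clusterThenMatch(valAct, cm, k = 4)))
    expect_gte(mean(a == b), 0.85)
})
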