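test_that("fold noise is multiplicative with the stated log2 distribution", {
    X <- withr::with_seed(1, matrix(rpois(200, 4), 20, 10))
    expect_identical(addFoldNoise(X, 0, seed = 1), X)
    X[1, ] <- 0
    Xn <- addFoldNoise(X, 1.5, seed = 2)
    expect_true(all(Xn[1, ] == 0))            # zeros stay zero
    expect_identical(addFoldNoise(X, 1.5, seed = 2), Xn)  # seeded
    expect_false(identical(addFoldNoise(X, 1.5, seed = 3), Xn))
    # Monte-Carlo: log2 ratios of 1e5 noised copies of 1 follow N(0, sigma)
    ones <- matrix(1, 1e5, 1)
    r <- log2(addFoldNoise(ones, 0.8, seed = 4))
    expect_lt(abs(mean(r)), 3 * 0.8 / sqrt(1e5))
    expect_lt(abs(sd(r) - 0.8) / 0.8, 0.02)
})

test_that("dropout corruptions zero the exact stated counts", {
    X <- withr::with_seed(2, matrix(rpois(300, 3), 30, 10))
    expect_identical(applyDropout(X, "gene", 0, seed = 1), X)
    Xg <- applyDropout(X, "gene", 0.5, seed = 1)
    expect_identical(sum(colSums(Xg) == 0), 5L)
    # value dropout: exact count among non-zeros, zeros untouched
    nz0 <- sum(X != 0)
    Xv <- applyDropout(X, "value", 0.3, seed = 1)
    expect_equal(sum(X != 0 & Xv == 0), round(0.3 * nz0))
    expect_true(all(Xv[X == 0] == 0))
    expect_true(all(Xv[Xv != 0] == X[Xv != 0]))
})

test_that("edge removal and insertion track the corrupted sets exactly", {
    tiny <- tinyTissue()
    g <- tiny$graph
    r0 <- removeEdges(g, 0, seed = 1)
    expect_identical(edges(r0$graph), edges(g))
    expect_identical(nrow(r0$removed), 0L)

    rem <- removeEdges(g, 0.5, seed = 1)
    expect_equal(nrow(rem$removed), round(0.5 * nEdges(g)))
    expect_identical(nEdges(rem$graph) + nrow(rem$removed), nEdges(g))
    expect_length(intersect(edgeKey(edges(rem$graph)),
                            edgeKey(rem$removed)), 0)
    expect_identical(removeEdges(g, 0.5, seed = 1)$removed, rem$removed)
    expect_error(removeEdges(cellGraph(cbind(1, 2), 4), 0.9), "training")

    add <- addFakeEdges(g, 2, seed = 1)
    expect_equal(nrow(add$fake), 2 * nEdges(g))
    expect_length(intersect(edgeKey(add$fake), edgeKey(edges(g))), 0)
    expect_equal(nEdges(add$graph), 3 * nEdges(g))
    a0 <- addFakeEdges(g, 0, seed = 1)
    expect_identical(edges(a0$graph), edges(g))
    # infeasible fold reports the maximum
    k5 <- cellGraph(t(combn(5L, 2L))[-1, ], nCells = 5)
    expect_error(addFakeEdges(k5, 10, seed = 1), "max fold")
})

test_that("pair-counting and trapezoidal AUROC agree and match brute force", {
    expect_equal(computeAUROC(c(0.9, 0.4), c(0.6, 0.1)), 0.75)
    expect_equal(computeAUROC(c(0.9, 0.4), c(0.6, 0.1), "trapezoid"),
                 0.75)
    expect_equal(computeAUROC(rep(1, 5), rep(0, 7)), 1)
    expect_equal(computeAUROC(rep(0.3, 5), rep(0.3, 7)), 0.5)
    for (s in 1:25) {
        pos <- withr::with_seed(s, round(runif(8), 2))
        neg <- withr::with_seed(s + 100, round(runif(11), 2))
        a <- computeAUROC(pos, neg)
        expect_equal(a, computeAUROC(pos, neg, "trapezoid"),
                     tolerance = 1e-12)
        expect_equal(a, bruteAUROC(pos, neg), tolerance = 1e-12)
        # invariance under a strictly monotone transform
        expect_equal(computeAUROC(qlogis(pmin(pmax(pos, .01), .99)),
                                  qlogis(pmin(pmax(neg, .01), .99))),
                     computeAUROC(pmin(pmax(pos, .01), .99),
                                  pmin(pmax(neg, .01), .99)),
                     tolerance = 1e-12)
    }
    expect_error(computeAUROC(numeric(0), 1), "non-empty")
})

test_that("AUPRC matches an explicit threshold sweep", {
    expect_equal(computeAUPRC(c(0.9, 0.8), c(0.2, 0.1)), 1)
    expect_lte(computeAUPRC(0, 1), 0.5)
    expect_equal(computeAUPRC(c(0.9, 0.4), c(0.6, 0.1)),
                 bruteAUPRC(c(0.9, 0.4), c(0.6, 0.1)))
    for (s in 1:25) {
        pos <- withr::with_seed(s, round(runif(7), 2))
        neg <- withr::with_seed(s + 200, round(runif(13), 2))
        expect_equal(computeAUPRC(pos, neg), bruteAUPRC(pos, neg),
                     tolerance = 1e-12)
    }
    expect_error(computeAUPRC(numeric(0), 1), "non-empty")
})

test_that("FPR at threshold counts boundary scores as positive calls", {
    neg <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
    expect_equal(computeFprAtThreshold(neg, 0.8), 0.3)
    expect_equal(computeFprAtThreshold(neg, 2), 0)
    expect_equal(computeFprAtThreshold(neg, -Inf), 1)
})

test_that("runBenchmark reproduces the per-benchmark scoring conventions", {
    sim <- simulateTissue(nCells = 90, nTypes = 3, nGenes = 20,
                          nInformative = 8, seed = 31)
    ds <- sim$dataset
    g <- buildAdjacency(spatialCoords(ds))
    cfg <- linkModelConfig(hidden = 12, latent = 6, discHidden = c(6, 6),
                           epochs = 25, normalizeFeatures = TRUE,
                           seed = 31)

    # magnitude 0 noise equals a plain train/evaluate run
    spec0 <- corruptionSpec("gaussian_fold_noise", 0, seed = 5)
    tab0 <- runBenchmark(ds, spec0, repeats = 1, config = cfg, graph = g)
    cfgR <- cfg; cfgR$seed <- spanet:::deriveSeed(5L, 1L)
    spR <- splitEdges(g, 0.1, 100, seed = cfgR$seed)
    fitR <- trainLinkModel(ds, spR, cfgR)
    HR <- latentMeans(fitR)
    expect_equal(tab0$auroc,
                 computeAUROC(spanet:::scoreEdges(HR, spR@testPos),
                              spanet:::scoreEdges(HR, spR@testNeg)))

    # grid x repeats shape
    spec2 <- corruptionSpec("value_dropout", c(0.1, 0.3), seed = 6)
    tab2 <- runBenchmark(ds, spec2, repeats = 2, config = cfg, graph = g)
    expect_identical(nrow(tab2), 4L)
    expect_identical(sort(unique(tab2$magnitude)), c(0.1, 0.3))

    # edge-removal scores exactly the removed set against an equal
    # number of never-existing pairs
    spec3 <- corruptionSpec("edge_removal", 0.3, seed = 7)
    tab3 <- runBenchmark(ds, spec3, repeats = 1, config = cfg, graph = g)
    expect_true(is.finite(tab3$auroc))
    seedR <- spanet:::deriveSeed(7L, 1L)
    rem <- removeEdges(g, 0.3, seed = seedR)
    spE <- splitEdges(rem$graph, 0, 0, seed = seedR)
    cfgE <- cfg; cfgE$seed <- seedR
    fitE <- trainLinkModel(ds, spE, cfgE)
    HE <- latentMeans(fitE)
    neg <- withr::with_seed(spanet:::deriveSeed(seedR, 7L),
        spanet:::pairDecode(spanet:::samplePairCodes(
            90, nrow(rem$removed),
            spanet:::edgeCodes(edges(g), 90)), 90))
    expect_equal(tab3$auroc,
                 computeAUROC(spanet:::scoreEdges(HE, rem$removed),
                              spanet:::scoreEdges(HE, neg)))
})
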