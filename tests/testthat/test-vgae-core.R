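test_that("normalized adjacency matches hand computation", {
    # single isolated cell: self-loop only
    g1 <- cellGraph(matrix(integer(0), 0, 2), nCells = 1)
    expect_equal(as.matrix(normalizeAdjacency(g1)),
                 matrix(1), ignore_attr = TRUE)
    # two connected cells: D = diag(2, 2), all entries 0.5
    g2 <- cellGraph(cbind(1, 2), nCells = 2)
    expect_equal(as.matrix(normalizeAdjacency(g2)),
                 matrix(0.5, 2, 2), ignore_attr = TRUE)
    # path 1-2-3: degrees + self-loops are (2, 3, 2)
    g3 <- cellGraph(rbind(c(1, 2), c(2, 3)), nCells = 3)
    At <- as.matrix(normalizeAdjacency(g3))
    expect_equal(At[1, 2], 1 / sqrt(6), tolerance = 1e-12)
    expect_equal(At[1, 1], 1 / 2, tolerance = 1e-12)
    expect_equal(At, t(At), tolerance = 1e-15)
    # an isolated cell inside a larger graph stays valid
    g4 <- cellGraph(cbind(1, 2), nCells = 3)
    expect_equal(as.matrix(normalizeAdjacency(g4))[3, 3], 1)
})

test_that("encoder forward pass matches a dense hand computation", {
    cfg <- linkModelConfig(hidden = 5, latent = 3,
                           discHidden = c(4, 4), seed = 3)
    params <- withr::with_seed(3, spanet:::initParams(4, cfg))
    g <- cellGraph(rbind(c(1, 2), c(2, 3), c(3, 4)), nCells = 4)
    At <- normalizeAdjacency(g)
    X <- withr::with_seed(4, matrix(rpois(16, 3), 4, 4))

    emb <- encodeCells(X, At, params)
    # independent dense reimplementation
    Ad <- as.matrix(At)
    hid <- pmax(Ad %*% X %*% params$W0, 0)
    mu <- Ad %*% hid %*% params$W1mu
    ls <- Ad %*% hid %*% params$W1sig
    expect_equal(latentMeans(emb), mu, tolerance = 1e-12)
    expect_equal(latentLogSigmas(emb), ls, tolerance = 1e-12)
    expect_equal(latentSample(emb), mu)   # eval mode: H = mu

    # all-zero features collapse everything to zero
    emb0 <- encodeCells(X * 0, At, params)
    expect_true(all(latentMeans(emb0) == 0))
    expect_true(all(latentSample(emb0) == 0))

    # eval mode is deterministic
    expect_identical(latentMeans(encodeCells(X, At, params)),
                     latentMeans(emb))
})

test_that("inner-product decoder has the closed-form sigmoid values", {
    H0 <- matrix(0, 3, 4)
    expect_true(all(decodeLatent(H0) == 0.5))
    # identical unit vectors: sigmoid(1)
    Hu <- rbind(c(1, 0), c(1, 0))
    expect_equal(decodeLatent(Hu)[1, 2], 1 / (1 + exp(-1)),
                 tolerance = 1e-12)
    # orthogonal vectors: 0.5
    Ho <- rbind(c(1, 0), c(0, 1))
    expect_equal(decodeLatent(Ho)[1, 2], 0.5)
    # symmetric to machine precision, invariant to rotation of H
    H <- withr::with_seed(5, matrix(rnorm(40), 8, 5))
    P <- decodeLatent(H)
    expect_equal(P, t(P), tolerance = 1e-14)
    Q <- qr.Q(qr(withr::with_seed(6, matrix(rnorm(25), 5, 5))))
    expect_equal(decodeLatent(H %*% Q), P, tolerance = 1e-12)
})

test_that("negative ELBO components follow the closed forms", {
    A <- matrix(0, 1, 1)
    # prior equals posterior: KL exactly 0
    z <- matrix(0, 1, 1)
    expect_equal(elboLoss(matrix(0.5, 1, 1), A, z, z)$kl, 0)
    # mu = 1, sigma = 1, one cell, one dim: KL = 1/2
    expect_equal(elboLoss(matrix(0.5, 1, 1), A, matrix(1), z)$kl, 0.5)
    # KL is non-negative and zero only at the prior
    for (s in 1:20) {
        mu <- withr::with_seed(s, matrix(rnorm(12), 3, 4))
        ls <- withr::with_seed(s + 50, matrix(rnorm(12, 0, 0.5), 3, 4))
        expect_gte(elboLoss(matrix(0.5, 3, 3), matrix(0, 3, 3),
                            mu, ls)$kl, 0)
    }
    # reconstruction term vanishes as probabilities approach the target
    A3 <- matrix(0, 3, 3); A3[1, 2] <- A3[2, 1] <- 1
    for (eps in c(1e-3, 1e-6, 1e-9)) {
        probs <- matrix(eps, 3, 3)
        probs[1, 2] <- probs[2, 1] <- 1 - eps
        diag(probs) <- 0.5
        r <- elboLoss(probs, A3, matrix(0, 3, 1), matrix(0, 3, 1))$recon
        expect_lt(r, 10 * eps)
    }
})

test_that("discriminator is a plain sigmoid MLP, order preserving", {
    cfg <- linkModelConfig(hidden = 4, latent = 3, discHidden = c(4, 5))
    params <- withr::with_seed(8, spanet:::initParams(4, cfg))
    H <- withr::with_seed(9, matrix(rnorm(21), 7, 3))
    p <- discriminatorForward(H, params)
    expect_length(p, 7)
    expect_true(all(p > 0 & p < 1))
    # dense hand computation
    r1 <- pmax(sweep(H %*% params$Wd1, 2, params$bd1, "+"), 0)
    r2 <- pmax(sweep(r1 %*% params$Wd2, 2, params$bd2, "+"), 0)
    pHand <- plogis(as.numeric(r2 %*% params$wd3 + params$bd3))
    expect_equal(p, pHand, tolerance = 1e-12)
    # zero weights: exactly 0.5 everywhere
    zero <- lapply(params, function(x) x * 0)
    expect_equal(discriminatorForward(H, zero), rep(0.5, 7))
    # order preserved under row permutation
    expect_equal(discriminatorForward(H[7:1, ], params), p[7:1])
})

test_that("training is seeded, improves over the untrained model, and logs", {
    sim <- simulateTissue(nCells = 100, nTypes = 3, nGenes = 24,
                          nInformative = 10, seed = 21)
    g <- buildAdjacency(spatialCoords(sim$dataset))
    sp <- splitEdges(g, 0.1, 30, seed = 21)
    cfg <- linkModelConfig(hidden = 16, latent = 8, discHidden = c(8, 8),
                           epochs = 40, normalizeFeatures = TRUE,
                           seed = 21, logEvery = 5)
    fit1 <- trainLinkModel(sim$dataset, sp, cfg)
    fit2 <- trainLinkModel(sim$dataset, sp, cfg)
    expect_identical(trainingLog(fit1), trainingLog(fit2))
    expect_identical(fit1@params$W0, fit2@params$W0)
    expect_identical(nrow(trainingLog(fit1)), 40L)

    # epochs = 0 returns the seeded initialization untouched
    cfg0 <- cfg; cfg0$epochs <- 0L
    fit0 <- trainLinkModel(sim$dataset, sp, cfg0)
    init <- withr::with_seed(21, spanet:::initParams(24, cfg))
    expect_identical(fit0@params$W0, init$W0)
    expect_identical(nrow(trainingLog(fit0)), 0L)

    # training beats the untrained encoder on held-out edges
    scoreOf <- function(fit) {
        H <- latentMeans(fit)
        computeAUROC(spanet:::scoreEdges(H, sp@testPos),
                     spanet:::scoreEdges(H, sp@testNeg))
    }
    expect_gt(scoreOf(fit1), scoreOf(fit0))
    # the log carries finite losses throughout
    expect_true(all(is.finite(trainingLog(fit1)$loss)))
})

test_that("trained link scores recover planted structure better than noise features", {
    st <- smallTrained()
    H <- latentMeans(st$fit)
    auroc <- computeAUROC(spanet:::scoreEdges(H, st$split@testPos),
                          spanet:::scoreEdges(H, st$split@testNeg))
    expect_gt(auroc, 0.8)

    # same pipeline with informative genes replaced by pure noise
    dsN <- st$ds
    X <- exprMatrix(dsN)
    inf <- informativeGenes(st$sim$truth)
    X[, inf] <- withr::with_seed(99,
        matrix(rpois(length(inf) * nrow(X), 2), nrow(X)))
    dsNoise <- SpatialCellExperiment(X, spatialCoords(dsN),
                                     cellTypes(dsN))
    fitN <- trainLinkModel(dsNoise, st$split, st$config)
    HN <- latentMeans(fitN)
    aurocN <- computeAUROC(spanet:::scoreEdges(HN, st$split@testPos),
                           spanet:::scoreEdges(HN, st$split@testNeg))
    expect_gt(auroc, aurocN)
})
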