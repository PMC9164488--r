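# minimal EdgeSplit with given test sets (helpers for threshold tests)
mkSplit <- function(testPos, testNeg, n) {
    methods::new("EdgeSplit", nCells = as.integer(n),
                 trainPos = matrix(integer(0), 0, 2),
                 testPos = spanet:::canonicalEdges(testPos),
                 testNeg = spanet:::canonicalEdges(testNeg),
                 negRatio = nrow(testNeg) / max(1, nrow(testPos)))
}

probsFrom <- function(n, entries) {
    P <- matrix(0.5, n, n)
    for (e in entries) {
        P[e[1], e[2]] <- e[3]; P[e[2], e[1]] <- e[3]
    }
    P
}

test_that("threshold selection maximizes test accuracy, ties to the top", {
    # separable: any t in (0.1, 0.9] is perfect; tie-break returns 0.9
    P <- probsFrom(4, list(c(1, 2, 0.9), c(3, 4, 0.1)))
    sp <- mkSplit(cbind(1, 2), cbind(3, 4), 4)
    expect_equal(selectThreshold(P, sp), 0.9)

    # the four-candidate sweep: brute-force oracle agrees
    P2 <- probsFrom(6, list(c(1, 2, 0.9), c(3, 4, 0.2),
                            c(1, 5, 0.6), c(2, 6, 0.1)))
    sp2 <- mkSplit(rbind(c(1, 2), c(3, 4)),
                   rbind(c(1, 5), c(2, 6)), 6)
    pos <- c(0.9, 0.2); neg <- c(0.6, 0.1)
    cand <- sort(unique(c(pos, neg)))
    acc <- sapply(cand, function(t)
        (sum(pos >= t) + sum(neg < t)) / 4)
    oracle <- max(cand[acc == max(acc)])
    expect_equal(selectThreshold(P2, sp2), oracle)

    # argmax contract on a random instance
    set.seed(12)
    n <- 20
    P3 <- decodeLatent(matrix(rnorm(n * 3), n, 3))
    tp <- spanet:::pairDecode(sample(n * (n - 1) / 2, 8), n)
    rest <- setdiff(seq_len(n * (n - 1) / 2),
                    spanet:::edgeCodes(tp, n))
    tn <- spanet:::pairDecode(sample(rest, 30), n)
    sp3 <- mkSplit(tp, tn, n)
    t3 <- selectThreshold(P3, sp3)
    accAt <- function(t) (sum(P3[sp3@testPos] >= t) +
                          sum(P3[sp3@testNeg] < t)) / 38
    for (t in unique(c(P3[sp3@testPos], P3[sp3@testNeg])))
        expect_gte(accAt(t3), accAt(t))

    # identical scores: degenerate with a warning
    P4 <- matrix(0.5, 4, 4)
    expect_warning(t4 <- selectThreshold(P4, sp), "identical")
    expect_equal(t4, 0.5)

    # balanced accuracy is exposed as an option
    expect_true(is.numeric(selectThreshold(P2, sp2, balanced = TRUE)))
})

test_that("network assembly respects the >= threshold and annotates edges", {
    coords <- cbind(c(0, 1, 2), c(0, 0, 0))
    P <- probsFrom(3, list(c(1, 2, 0.8), c(1, 3, 0.3), c(2, 3, 0.6)))
    net <- assembleNetwork(P, 0.5, coords)
    expect_identical(edgeKey(edges(net)), c("1 2", "2 3"))
    expect_equal(edgeTable(net)$distance, c(1, 1))

    # boundary: probabilities exactly at the threshold are kept
    netAll <- assembleNetwork(decodeLatent(matrix(0, 3, 2)), 0.5, coords)
    expect_identical(nEdges(netAll), 3L)
    # threshold above every sigmoid output: empty network
    netNone <- assembleNetwork(P, 0.99, coords)
    expect_identical(nEdges(netNone), 0L)
    # raising the threshold never adds edges
    for (t in c(0.3, 0.55, 0.7, 0.9)) {
        lo <- assembleNetwork(P, t, coords)
        hi <- assembleNetwork(P, min(t + 0.2, 1), coords)
        expect_true(all(edgeKey(edges(hi)) %in% edgeKey(edges(lo))))
    }
    # original-adjacency membership annotation
    g <- cellGraph(cbind(1, 2), 3)
    netG <- assembleNetwork(P, 0.5, coords, graph = g)
    tab <- edgeTable(netG)
    expect_identical(tab$in_original[tab$i == 1 & tab$j == 2], TRUE)
    expect_identical(tab$in_original[tab$i == 2 & tab$j == 3], FALSE)
})

test_that("distal classification partitions edges by the distance cutoff", {
    # unit line with one long-range edge
    coords <- cbind(0:5, 0)
    P <- probsFrom(6, list(c(1, 2, 0.9), c(2, 3, 0.9), c(3, 4, 0.9),
                           c(4, 5, 0.9), c(5, 6, 0.9), c(1, 6, 0.9)))
    net <- assembleNetwork(P, 0.9, coords)
    cls <- classifyDistal(net, cutoff = 2)
    tab <- edgeTable(cls)
    expect_identical(tab[tab$is_distal, c("i", "j")],
                     tab[tab$distance == 5, c("i", "j")])
    expect_identical(sum(tab$is_distal), 1L)

    expect_identical(sum(edgeTable(
        classifyDistal(net, cutoff = Inf))$is_distal), 0L)
    expect_identical(sum(edgeTable(
        classifyDistal(net, cutoff = 0))$is_distal), 6L)

    # auto cutoff: 95th percentile of the reference contact distances
    ref <- c(1, 1, 1, 1, 2)
    auto <- classifyDistal(net, cutoff = "auto",
                           referenceDistances = ref)
    expect_equal(auto@distalCutoff, quantile(ref, 0.95, names = FALSE))
    expect_error(classifyDistal(net, cutoff = "auto"), "reference")
})

test_that("probability-distance correlation behaves at the extremes", {
    set.seed(3)
    coords <- cbind(runif(15), runif(15))
    d <- as.matrix(dist(coords))
    # probability strictly decreasing in distance: rho = -1
    P <- 1 / (1 + d); diag(P) <- 1
    res <- distanceProbabilityCorrelation(P, coords)
    expect_equal(res$correlation, -1)
    expect_equal(nrow(res$table), 15 * 14 / 2)
    # permuted probabilities: near-zero correlation on average
    rhos <- sapply(1:20, function(s) {
        Pp <- P
        up <- upper.tri(Pp)
        Pp[up] <- withr::with_seed(s, sample(Pp[up]))
        Pp[lower.tri(Pp)] <- t(Pp)[lower.tri(Pp)]
        distanceProbabilityCorrelation(Pp, coords)$correlation
    })
    expect_lt(abs(mean(rhos)), 0.1)
})

test_that("assembly at the selected threshold dominates the 0.5 default", {
    st <- smallTrained()
    P <- decodeLatent(latentMeans(st$fit))
    thr <- selectThreshold(P, st$split)
    accAt <- function(t) {
        sp <- P[st$split@testPos]; sn <- P[st$split@testNeg]
        (sum(sp >= t) + sum(sn < t)) / (length(sp) + length(sn))
    }
    expect_gte(accAt(thr), accAt(0.5))
})
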