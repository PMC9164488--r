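#' @include AllClasses.R
NULL

#' Multiplicative fold-change noise on expression
#'
#' Each entry is independently multiplied by `2^r` with
#' `r ~ N(0, sigma)`, i.e. the log2 fold change of noised over original
#' expression is normal with standard deviation `sigma`. Zeros stay
#' zero (the noise is multiplicative); the input is not modified.
#'
#' @param X expression matrix (cells x genes)
#' @param sigma standard deviation of the log2 fold change (>= 0)
#' @param seed integer seed
#' @return the noised matrix
#' @export
addFoldNoise <- function(X, sigma, seed = 1L) {
    stopifnot(sigma >= 0)
    if (sigma == 0) return(X)
    withr::with_seed(as.integer(seed),
        X * 2^matrix(rnorm(length(X), 0, sigma), nrow(X), ncol(X)))
}

#' Simulated dropout on expression
#'
#' `kind = "gene"` removes whole genes: `round(fraction * nGenes)`
#' randomly chosen columns are zeroed. `kind = "value"` zeroes
#' `round(fraction * #nonzero)` randomly picked currently non-zero
#' entries; entries that are already zero are never touched.
#'
#' @param X expression matrix (cells x genes)
#' @param kind `"gene"` or `"value"`
#' @param fraction fraction in `[0, 1)` of the pool (genes or non-zero
#'   values) to zero
#' @param seed integer seed
#' @return the corrupted matrix
#' @export
applyDropout <- function(X, kind = c("gene", "value"), fraction,
                         seed = 1L) {
    kind <- match.arg(kind)
    stopifnot(fraction >= 0, fraction < 1)
    if (fraction == 0) return(X)
    withr::with_seed(as.integer(seed), {
        if (kind == "gene") {
            nDrop <- round(fraction * ncol(X))
            X[, sample.int(ncol(X), nDrop)] <- 0
        } else {
            nz <- which(X != 0)
            nDrop <- round(fraction * length(nz))
            X[sample(nz, nDrop)] <- 0
        }
        X
    })
}

#' Randomly delete edges from a graph
#'
#' Uniform sampling without replacement; `round(fraction * nEdges)`
#' edges are removed and returned alongside the reduced graph, so that
#' their recovery can be scored.
#'
#' @param graph a [CellGraph-class]
#' @param fraction fraction of edges to remove, in `[0, 1)`
#' @param seed integer seed
#' @return list with `graph` (reduced [CellGraph-class]) and `removed`
#'   (edge matrix)
#' @export
removeEdges <- function(graph, fraction, seed = 1L) {
    stopifnot(fraction >= 0, fraction < 1)
    e <- edges(graph)
    nDrop <- round(fraction * nrow(e))
    if (nrow(e) - nDrop < 1L)
        stop("removal would leave no training edges")
    withr::with_seed(as.integer(seed), {
        drop <- if (nDrop > 0) sample.int(nrow(e), nDrop) else integer(0)
        list(graph = cellGraph(e[setdiff(seq_len(nrow(e)), drop), ,
                                 drop = FALSE], nCells(graph)),
             removed = canonicalEdges(e[drop, , drop = FALSE]))
    })
}

#' Randomly insert fake edges into a graph
#'
#' Adds `round(fold * nEdges)` distinct non-edges (uniformly sampled,
#' self-pairs excluded) and returns them alongside the augmented graph,
#' so that real and fake edges can be scored against each other.
#'
#' @param graph a [CellGraph-class]
#' @param fold number of fakes relative to the existing edge count
#'   (the benchmarks use 1-10)
#' @param seed integer seed
#' @return list with `graph` (augmented [CellGraph-class]) and `fake`
#'   (edge matrix)
#' @export
addFakeEdges <- function(graph, fold, seed = 1L) {
    stopifnot(fold >= 0)
    e <- edges(graph)
    n <- nCells(graph)
    nFake <- round(fold * nrow(e))
    nonEdges <- n * (n - 1) / 2 - nrow(e)
    if (nFake > nonEdges)
        stop(sprintf(
            "requested %d fake edges but only %d non-edges exist (max fold %.2f)",
            nFake, nonEdges, nonEdges / max(nrow(e), 1L)))
    if (nFake == 0)
        return(list(graph = graph,
                    fake = matrix(integer(0), 0L, 2L,
                                  dimnames = list(NULL, c("i", "j")))))
    withr::with_seed(as.integer(seed), {
        fake <- pairDecode(samplePairCodes(n, nFake, edgeCodes(e, n)), n)
        list(graph = cellGraph(rbind(e, fake), n),
             fake = canonicalEdges(fake))
    })
}

#' Corruption specification for [runBenchmark()]
#'
#' @param kind one of `"gaussian_fold_noise"`, `"gene_dropout"`,
#'   `"value_dropout"`, `"edge_removal"`, `"edge_addition"`, `"crop"`
#' @param magnitude non-negative; a sigma (noise), a fraction
#'   (dropout/removal/crop window side), or a fold (addition, <= 10);
#'   may be a vector to sweep a grid
#' @param seed base seed; repeat r of magnitude m uses a seed derived
#'   from it
#' @return a classed list
#' @export
corruptionSpec <- function(kind = c("gaussian_fold_noise", "gene_dropout",
                                    "value_dropout", "edge_removal",
                                    "edge_addition", "crop"),
                           magnitude, seed = 1L) {
    kind <- match.arg(kind)
    stopifnot(all(magnitude >= 0))
    if (kind %in% c("gene_dropout", "value_dropout", "edge_removal",
                    "crop"))
        stopifnot(all(magnitude < 1))
    if (kind == "edge_addition") stopifnot(all(magnitude <= 10))
    structure(list(kind = kind, magnitude = magnitude,
                   seed = as.integer(seed)),
              class = "corruptionSpec")
}

#' Corruption benchmark: corrupt, retrain, score
#'
#' Reproduces the robustness protocol: for each magnitude on the grid
#' and each repeat (with a seed derived as `base + repeat`), the input
#' is corrupted, the model is retrained from scratch, and the
#' benchmark-specific sets are scored:
#'
#' * `edge_removal`: removed edges (positives) vs an equal number of
#'   originally non-existing edges (negatives);
#' * `edge_addition`: pre-existing real edges (positives) vs the
#'   mixed-in fakes (negatives);
#' * expression corruptions and `crop`: the held-out 90/10 split with
#'   its 100x negative set.
#'
#' For `crop`, the magnitude is the linear size of a random
#' sub-rectangle relative to the full field.
#'
#' @param ds a [SpatialCellExperiment-class]
#' @param corruption a [corruptionSpec()]
#' @param repeats independent corruption/training repeats per magnitude
#' @param config a [linkModelConfig()]
#' @param graph optional precomputed [CellGraph-class] (built from the
#'   coordinates when missing)
#' @return tidy data.frame: `repeat_`, `kind`, `magnitude`, `auroc`,
#'   `auprc`, `fpr`
#' @export
runBenchmark <- function(ds, corruption, repeats = 30L,
                         config = linkModelConfig(), graph = NULL) {
    stopifnot(inherits(corruption, "corruptionSpec"), repeats >= 1L)
    if (is.null(graph))
        graph <- buildAdjacency(spatialCoords(ds))
    rows <- list()
    for (mag in corruption$magnitude) {
        for (r in seq_len(repeats)) {
            seedR <- deriveSeed(corruption$seed, r)
            res <- benchmarkOnce(ds, graph, corruption$kind, mag, seedR,
                                 config)
            rows[[length(rows) + 1L]] <- data.frame(
                repeat_ = r, kind = corruption$kind, magnitude = mag,
                auroc = res$auroc, auprc = res$auprc, fpr = res$fpr)
        }
    }
    do.call(rbind, rows)
}

benchmarkOnce <- function(ds, graph, kind, mag, seedR, config) {
    config$seed <- seedR
    n <- nCells(ds)
    if (kind %in% c("gaussian_fold_noise", "gene_dropout",
                    "value_dropout", "crop")) {
        dsC <- ds; graphC <- graph
        if (kind == "gaussian_fold_noise") {
            X <- addFoldNoise(exprMatrix(ds), mag, seedR)
        } else if (kind != "crop") {
            X <- applyDropout(exprMatrix(ds),
                              sub("_dropout", "", kind), mag, seedR)
        } else {
            xy <- spatialCoords(ds)
            wx <- diff(range(xy[, 1L])) * mag
            wy <- diff(range(xy[, 2L])) * mag
            xy0 <- withr::with_seed(seedR, c(
                runif(1, min(xy[, 1L]), max(xy[, 1L]) - wx),
                runif(1, min(xy[, 2L]), max(xy[, 2L]) - wy)))
            dsC <- cropField(ds, c(xy0[1L], xy0[1L] + wx),
                             c(xy0[2L], xy0[2L] + wy))
            graphC <- buildAdjacency(spatialCoords(dsC))
            X <- exprMatrix(dsC)
        }
        if (kind != "crop")
            dsC <- SpatialCellExperiment(X, spatialCoords(ds),
                                         cellTypes(ds), geneNames(ds),
                                         cellIds(ds))
        split <- splitEdges(graphC, 0.1, 100, seed = seedR)
        fit <- trainLinkModel(dsC, split, config)
        H <- latentMeans(fit)
        sp <- scoreEdges(H, split@testPos)
        sn <- scoreEdges(H, split@testNeg)
        thr <- selectThreshold(decodeLatent(H), split)
        return(list(auroc = computeAUROC(sp, sn),
                    auprc = computeAUPRC(sp, sn),
                    fpr = computeFprAtThreshold(sn, thr)))
    }
    if (kind == "edge_removal") {
        rem <- removeEdges(graph, mag, seedR)
        split <- splitEdges(rem$graph, testFraction = 0, negRatio = 0,
                            seed = seedR)
        fit <- trainLinkModel(ds, split, config)
        H <- latentMeans(fit)
        # equal number of never-existing edges as the negative set
        excl <- edgeCodes(edges(graph), n)
        neg <- withr::with_seed(deriveSeed(seedR, 7L), pairDecode(
            samplePairCodes(n, nrow(rem$removed), excl), n))
        sp <- scoreEdges(H, rem$removed)
        sn <- scoreEdges(H, neg)
    } else {                               # edge_addition
        add <- addFakeEdges(graph, mag, seedR)
        split <- splitEdges(add$graph, testFraction = 0, negRatio = 0,
                            seed = seedR)
        fit <- trainLinkModel(ds, split, config)
        H <- latentMeans(fit)
        sp <- scoreEdges(H, edges(graph))
        sn <- scoreEdges(H, add$fake)
    }
    list(auroc = computeAUROC(sp, sn), auprc = computeAUPRC(sp, sn),
         fpr = computeFprAtThreshold(sn, 0.5))
}
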