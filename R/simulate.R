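#' @include AllClasses.R
NULL

#' Simulate a spatial transcriptome section with planted interactions
#'
#' Generates a planar tissue emulating the structure of single-cell
#' spatial transcriptome sections: cells on a jittered grid (near-regular
#' packing, unit mean spacing), spatially coherent cell-type territories,
#' a 3-nearest-neighbor contact graph as the planted interaction set,
#' and an expression matrix in which the interaction structure is
#' statistically encoded.
#'
#' Each cell carries a latent state built from a smooth spatial random
#' field (Gaussian bumps at random centers) plus a cell-type offset.
#' Informative genes are Poisson with a log-linear dependence on that
#' latent state, so interacting (nearby, like-typed) cells have
#' correlated expression; the remaining genes are pure Poisson noise
#' with no spatial structure. Technical dropout zeroes each entry
#' independently with probability `dropoutRate`.
#'
#' Under `edgeRule = "proximity_plus_type_affinity"` an extra
#' `distalFraction` of planted edges is added between random same-type
#' non-neighboring cells, giving ground-truth distal interactions for
#' recovery tests.
#'
#' @param nCells number of cells (>= 4; 200-5000 is the intended range)
#' @param nTypes number of cell types
#' @param nGenes total number of genes
#' @param nInformative number of genes tied to the latent state
#'   (`<= nGenes`; the rest are noise)
#' @param edgeRule `"proximity"` (3-NN contacts only) or
#'   `"proximity_plus_type_affinity"`
#' @param dropoutRate per-entry zeroing probability in `[0, 1)`
#' @param seed integer; the whole simulation is bit-reproducible from it
#' @param distalFraction fraction of extra same-type distal edges under
#'   the affinity rule
#' @return a list with elements `dataset`
#'   ([SpatialCellExperiment-class]) and `truth`
#'   ([SyntheticTruth-class])
#' @examples
#' sim <- simulateTissue(nCells = 100, nGenes = 30, seed = 1)
#' sim$dataset
#' sim$truth
#' @export
simulateTissue <- function(nCells = 500L, nTypes = 5L, nGenes = 60L,
                           nInformative = 20L,
                           edgeRule = c("proximity",
                                        "proximity_plus_type_affinity"),
                           dropoutRate = 0.3, seed = 1L,
                           distalFraction = 0.05) {
    edgeRule <- match.arg(edgeRule)
    if (nCells < 4L)
        stop("nCells must be >= 4 to form a 3-nearest-neighbor graph")
    stopifnot(nInformative <= nGenes, nInformative >= 0L,
              dropoutRate >= 0, dropoutRate < 1, nTypes >= 1L)

    # generator constants (the emulated study conditions; see the
    # methods vignette for rationale)
    latentDim <- 8L
    nCenters <- 10L
    baseMean <- 2
    signalStrength <- 1.2
    typeStrength <- 1
    typeNoise <- 0.05
    lambdaCap <- 50

    withr::with_seed(as.integer(seed), {
        # jittered grid, unit spacing
        m <- ceiling(sqrt(nCells))
        grid <- expand.grid(gx = seq_len(m), gy = seq_len(m))
        keep <- sample.int(nrow(grid), nCells)
        coords <- cbind(x = grid$gx[keep] + runif(nCells, -0.3, 0.3),
                        y = grid$gy[keep] + runif(nCells, -0.3, 0.3))
        side <- m

        # spatially coherent type territories: nearest of nTypes seeds,
        # with a small fraction of random reassignments
        seeds <- cbind(runif(nTypes, 1, side), runif(nTypes, 1, side))
        d2seed <- outer(coords[, 1L], seeds[, 1L], "-")^2 +
            outer(coords[, 2L], seeds[, 2L], "-")^2
        type <- max.col(-d2seed)
        flip <- runif(nCells) < typeNoise
        type[flip] <- sample.int(nTypes, sum(flip), replace = TRUE)
        typeLabels <- paste0("T", type)

        # planted interactions: 3-NN contact graph (+ optional distal)
        graph <- buildAdjacency(coords, k = 3L, distanceThreshold = Inf)
        e <- edges(graph)
        if (edgeRule == "proximity_plus_type_affinity") {
            nExtra <- round(distalFraction * nrow(e))
            if (nExtra > 0) {
                same <- outer(type, type, "==")
                same[lower.tri(same, diag = TRUE)] <- FALSE
                cand <- which(same, arr.ind = TRUE)   # row < col
                cand <- cbind(i = cand[, 1L], j = cand[, 2L])
                codes <- pairCode(cand[, 1L], cand[, 2L], nCells)
                cand <- cand[!(codes %in% edgeCodes(e, nCells)), ,
                             drop = FALSE]
                # favor genuinely distal pairs
                len <- edgeLengths(cand, coords)
                cand <- cand[len > 2 * stats::median(edgeLengths(e, coords)),
                             , drop = FALSE]
                pick <- sample.int(nrow(cand), min(nExtra, nrow(cand)))
                e <- canonicalEdges(rbind(e, cand[pick, , drop = FALSE]))
            }
        }

        # latent state: smooth spatial field + type offset
        centers <- cbind(runif(nCenters, 1, side), runif(nCenters, 1, side))
        ell <- side / 4
        k <- exp(-(outer(coords[, 1L], centers[, 1L], "-")^2 +
                   outer(coords[, 2L], centers[, 2L], "-")^2) /
                 (2 * ell^2))
        v <- matrix(rnorm(nCenters * latentDim), nCenters, latentDim)
        z <- k %*% v
        z <- scale(z)[, , drop = FALSE]          # per-dim mean 0, sd 1
        typeVec <- matrix(rnorm(nTypes * latentDim), nTypes, latentDim)
        z <- z + typeStrength * typeVec[type, , drop = FALSE]

        # expression: informative genes log-linear in z, rest noise
        informative <- if (nInformative > 0)
            sort(sample.int(nGenes, nInformative)) else integer(0)
        expr <- matrix(0, nCells, nGenes)
        if (nInformative > 0) {
            loadings <- matrix(rnorm(latentDim * nInformative),
                               latentDim, nInformative)
            # equalize per-gene signal magnitude (random direction,
            # fixed norm): every informative gene genuinely depends on
            # the latent state, so the planted labels are a valid
            # recovery oracle
            loadings <- sweep(loadings, 2L,
                              sqrt(colSums(loadings^2) / latentDim),
                              "/")
            eta <- (z %*% loadings) / sqrt(latentDim)
            lambda <- pmin(baseMean * exp(signalStrength * eta), lambdaCap)
            expr[, informative] <- rpois(nCells * nInformative, lambda)
        }
        noiseGenes <- setdiff(seq_len(nGenes), informative)
        if (length(noiseGenes)) {
            lamNoise <- runif(length(noiseGenes), 0.5, 3)
            expr[, noiseGenes] <- rpois(
                nCells * length(noiseGenes),
                rep(lamNoise, each = nCells))
        }
        if (dropoutRate > 0) {
            drop <- runif(length(expr)) < dropoutRate
            expr[drop] <- 0
        }

        ds <- SpatialCellExperiment(
            expression = expr, coordinates = coords,
            cellTypes = typeLabels,
            geneNames = sprintf("gene%03d", seq_len(nGenes)),
            cellIds = sprintf("cell%04d", seq_len(nCells)))
        truth <- methods::new(
            "SyntheticTruth",
            trueEdges = e,
            informativeGenes = as.integer(informative),
            generatorParams = list(
                n_cells = nCells, n_types = nTypes, n_genes = nGenes,
                n_informative = nInformative, edge_rule = edgeRule,
                dropout_rate = dropoutRate, seed = as.integer(seed),
                distal_fraction = distalFraction,
                latent_dim = latentDim, n_centers = nCenters,
                base_mean = baseMean, signal_strength = signalStrength,
                type_strength = typeStrength, type_noise = typeNoise,
                lambda_cap = lambdaCap))
        list(dataset = ds, truth = truth)
    })
}
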