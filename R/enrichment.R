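#' @include AllClasses.R
NULL

# integer encoding of unordered type pairs over T types:
# (a, b) with a <= b  ->  (a - 1) * T + b ; tabulate-friendly
typePairId <- function(ta, tb, nT) {
    a <- pmin(ta, tb); b <- pmax(ta, tb)
    (a - 1L) * nT + b
}

allTypePairs <- function(levelsT) {
    nT <- length(levelsT)
    idx <- which(upper.tri(diag(nT), diag = TRUE), arr.ind = TRUE)
    data.frame(type_a = levelsT[idx[, 1L]], type_b = levelsT[idx[, 2L]],
               .a = idx[, 1L], .b = idx[, 2L])
}

#' Count interactions per cell-type pair
#'
#' Each edge contributes once, to the unordered pair of its endpoint
#' types (within-type pairs included). All type pairs are reported,
#' zeros kept.
#'
#' @param edges two-column integer edge matrix (1-based cell indices)
#' @param cellTypes per-cell type labels covering every referenced
#'   cell
#' @return data.frame `type_a`, `type_b`, `count`
#' @export
countTypeInteractions <- function(edges, cellTypes) {
    stopifnot(!anyNA(cellTypes))
    lv <- sort(unique(as.character(cellTypes)))
    ti <- match(as.character(cellTypes), lv)
    nT <- length(lv)
    pairs <- allTypePairs(lv)
    counts <- integer(nrow(pairs))
    if (nrow(edges)) {
        id <- typePairId(ti[edges[, 1L]], ti[edges[, 2L]], nT)
        tab <- tabulate(id, nbins = nT * nT)
        counts <- tab[typePairId(pairs$.a, pairs$.b, nT)]
    }
    data.frame(type_a = pairs$type_a, type_b = pairs$type_b,
               count = counts)
}

# shared machinery: observed counts vs a nPerm x nPairs null matrix
enrichmentFromNull <- function(obsCounts, nullCounts, pairs, typeSizes,
                               nPermutations) {
    nullMean <- colMeans(nullCounts)
    nullSd <- apply(nullCounts, 2L, stats::sd)
    cntGE <- colSums(sweep(nullCounts, 2L, obsCounts, ">="))
    cntLE <- colSums(sweep(nullCounts, 2L, obsCounts, "<="))
    pOne <- (1 + pmin(cntGE, cntLE)) / (nPermutations + 1)
    pTwo <- pmin(1, 2 * pOne)
    direction <- ifelse(obsCounts > nullMean, "enriched",
                        ifelse(obsCounts < nullMean, "depleted",
                               "neutral"))
    nA <- typeSizes[pairs$.a]
    nB <- typeSizes[pairs$.b]
    connectivity <- ifelse(
        pairs$.a == pairs$.b,
        ifelse(nA >= 2, obsCounts / (nA * (nA - 1) / 2), NA_real_),
        obsCounts / (nA * nB))
    data.frame(
        type_a = pairs$type_a, type_b = pairs$type_b,
        observed_count = obsCounts, connectivity = connectivity,
        null_mean = nullMean, null_sd = nullSd, p_two_tail = pTwo,
        direction = direction,
        signed_log10_p = ifelse(direction == "depleted", -1, 1) *
            -log10(pTwo))
}

#' Permutation test for cell-type interaction enrichment
#'
#' Tests, per unordered cell-type pair, whether the network contains
#' more (enrichment) or fewer (depletion) interactions than expected by
#' chance. Null networks keep the node set, the type labels and the
#' edge count, with edges re-drawn uniformly at random among all cell
#' pairs (default) or rewired degree-preservingly
#' (`method = "degree_preserving"`). P-values use the add-one
#' convention, `p_one = (1 + #more-extreme) / (n_perm + 1)`, doubled
#' for the two-tailed test (capped at 1), so they are never 0.
#'
#' @param edges two-column integer edge matrix (e.g.
#'   `edges(network)` of a reconstructed network)
#' @param cellTypes per-cell type labels (>= 2 distinct types)
#' @param nCellsTotal number of cells (defaults to
#'   `length(cellTypes)`)
#' @param nPermutations number of null networks (default 1000; below
#'   100 a warning is attached to the result)
#' @param seed integer seed
#' @param method `"uniform"` re-draw or `"degree_preserving"`
#'   double-edge swaps
#' @return data.frame with one row per type pair: `type_a`, `type_b`,
#'   `observed_count`, `connectivity` (count over the product of type
#'   sizes, or over the within-type pair count), `null_mean`,
#'   `null_sd`, `p_two_tail`, `direction`, `signed_log10_p`
#' @export
permutationTest <- function(edges, cellTypes,
                            nCellsTotal = length(cellTypes),
                            nPermutations = 1000L, seed = 1L,
                            method = c("uniform", "degree_preserving")) {
    method <- match.arg(method)
    lv <- sort(unique(as.character(cellTypes)))
    if (length(lv) < 2L) stop("need at least 2 cell types")
    ti <- match(as.character(cellTypes), lv)
    nT <- length(lv)
    pairs <- allTypePairs(lv)
    pairIdx <- typePairId(pairs$.a, pairs$.b, nT)
    m <- nrow(edges)
    n <- nCellsTotal

    obs <- countTypeInteractions(edges, cellTypes)$count

    nullCounts <- withr::with_seed(as.integer(seed), {
        if (method == "uniform") {
            t(vapply(seq_len(nPermutations), function(p) {
                e <- pairDecode(samplePairCodes(n, m), n)
                tabulate(typePairId(ti[e[, 1L]], ti[e[, 2L]], nT),
                         nbins = nT * nT)[pairIdx]
            }, numeric(length(pairIdx))))
        } else {
            g0 <- igraph::graph_from_edgelist(edges, directed = FALSE)
            g0 <- igraph::add_vertices(
                g0, max(0L, n - igraph::vcount(g0)))
            t(vapply(seq_len(nPermutations), function(p) {
                g <- igraph::rewire(
                    g0, igraph::keeping_degseq(niter = 10L * m))
                e <- igraph::as_edgelist(g)
                tabulate(typePairId(ti[e[, 1L]], ti[e[, 2L]], nT),
                         nbins = nT * nT)[pairIdx]
            }, numeric(length(pairIdx))))
        }
    })
    out <- enrichmentFromNull(obs, nullCounts, pairs,
                              tabulate(ti, nT), nPermutations)
    if (nPermutations < 100L)
        attr(out, "warning") <-
            sprintf("only %d permutations; p-value resolution is %.3g",
                    nPermutations, 1 / (nPermutations + 1))
    out
}

#' Permutation test restricted to distal interactions
#'
#' Same machinery as [permutationTest()], but the null draws the same
#' number of interactions uniformly from the cell pairs whose distance
#' exceeds `distalCutoff`, testing enrichment or depletion of distal
#' interactions per type pair.
#'
#' @param distalEdges two-column integer edge matrix of the distal
#'   edges (e.g. the distal partition of a classified network)
#' @param coords per-cell coordinate matrix (all cells)
#' @param distalCutoff distance above which a pair counts as distal
#' @param cellTypes per-cell type labels
#' @param nPermutations,seed as in [permutationTest()]
#' @return as [permutationTest()]
#' @export
distalPermutationTest <- function(distalEdges, coords, distalCutoff,
                                  cellTypes, nPermutations = 1000L,
                                  seed = 1L) {
    lv <- sort(unique(as.character(cellTypes)))
    if (length(lv) < 2L) stop("need at least 2 cell types")
    ti <- match(as.character(cellTypes), lv)
    nT <- length(lv)
    n <- nrow(coords)
    m <- nrow(distalEdges)
    if (m < 1L) stop("no distal edges to test")

    # dist() enumerates pairs in the same order as pairCode()
    candCodes <- which(as.numeric(stats::dist(coords)) > distalCutoff)
    if (length(candCodes) < m)
        stop(sprintf(
            "only %d candidate distal pairs for %d distal edges",
            length(candCodes), m))
    pairs <- allTypePairs(lv)
    pairIdx <- typePairId(pairs$.a, pairs$.b, nT)
    obs <- countTypeInteractions(distalEdges, cellTypes)$count
    nullCounts <- withr::with_seed(as.integer(seed), {
        t(vapply(seq_len(nPermutations), function(p) {
            e <- pairDecode(sample(candCodes, m), n)
            tabulate(typePairId(ti[e[, 1L]], ti[e[, 2L]], nT),
                     nbins = nT * nT)[pairIdx]
        }, numeric(length(pairIdx))))
    })
    enrichmentFromNull(obs, nullCounts, pairs, tabulate(ti, nT),
                       nPermutations)
}

#' Per-cell edge-distance null comparison
#'
#' For one cell, compares the distances of its reconstructed partners
#' to the distances obtained when the same number of partners is picked
#' uniformly at random, over `nShuffles` shuffles. The one-sided rank
#' p-value asks whether the observed mean partner distance is shorter
#' than random.
#'
#' @param cell 1-based cell index with at least one edge
#' @param network a [ReconstructedNetwork-class] (or a two-column edge
#'   matrix)
#' @param coords per-cell coordinate matrix
#' @param nShuffles number of random partner draws
#' @param seed integer seed
#' @return list with `observed` (distances, length = degree), `null`
#'   (nShuffles x degree matrix) and `p` (one-sided rank p-value)
#' @export
edgeDistanceNull <- function(cell, network, coords, nShuffles = 1000L,
                             seed = 1L) {
    e <- if (methods::is(network, "ReconstructedNetwork"))
        edges(network) else network
    partners <- c(e[e[, 1L] == cell, 2L], e[e[, 2L] == cell, 1L])
    if (!length(partners)) stop("cell has no edges")
    n <- nrow(coords)
    obs <- sqrt(colSums((t(coords[partners, , drop = FALSE]) -
                         coords[cell, ])^2))
    others <- setdiff(seq_len(n), cell)
    nullM <- withr::with_seed(as.integer(seed), {
        m <- vapply(seq_len(nShuffles), function(s) {
            p <- sample(others, length(partners))
            sqrt(colSums((t(coords[p, , drop = FALSE]) -
                          coords[cell, ])^2))
        }, numeric(length(partners)))
        if (is.null(dim(m))) matrix(m, ncol = 1L) else t(m)
    })
    p <- (1 + sum(rowMeans(nullM) <= mean(obs))) / (nShuffles + 1)
    list(observed = obs, null = nullM, p = p)
}

#' Per-cell degree in a network
#'
#' Hub cells are simply the cells with unusually high degree in the
#' reconstructed network; this helper returns the degree of every cell.
#'
#' @param network a [ReconstructedNetwork-class] or [CellGraph-class]
#' @return integer vector of length nCells
#' @export
cellDegrees <- function(network) {
    e <- edges(network)
    n <- if (methods::is(network, "ReconstructedNetwork"))
        network@nCells else nCells(network)
    tabulate(c(e[, 1L], e[, 2L]), nbins = n)
}
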