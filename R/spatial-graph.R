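#' @include AllClasses.R
NULL

# blockwise k-nearest neighbors (indices + distances), ties broken by
# ascending cell index; avoids materializing the full distance matrix
# for large sections
knnNeighbors <- function(coords, k, blockSize = 512L) {
    n <- nrow(coords)
    stopifnot(n >= k + 1L)
    idx <- matrix(0L, n, k)
    dst <- matrix(0, n, k)
    for (start in seq(1L, n, by = blockSize)) {
        rows <- start:min(start + blockSize - 1L, n)
        d2 <- outer(coords[rows, 1L], coords[, 1L], "-")^2 +
            outer(coords[rows, 2L], coords[, 2L], "-")^2
        for (r in seq_along(rows)) {
            i <- rows[r]
            di <- d2[r, ]
            di[i] <- Inf
            o <- order(di, seq_len(n))[seq_len(k)]
            idx[i, ] <- o
            dst[i, ] <- sqrt(di[o])
        }
    }
    list(index = idx, distance = dst)
}

#' Pairwise and nearest-neighbor distance distributions
#'
#' Summarizes the cell-to-cell distance structure of a section: the
#' full multiset of pairwise Euclidean distances and, per cell, the
#' distances to its `k` nearest neighbors. These distributions are the
#' basis for choosing the direct-contact distance threshold.
#'
#' @param coords numeric matrix of per-cell x/y coordinates (>= 2 rows;
#'   >= `k + 1` rows for the neighbor part)
#' @param k number of nearest neighbors to report (default 3)
#' @return list with `allPairs` (numeric vector, length n(n-1)/2) and
#'   `knn` (n x k matrix of neighbor distances, nearest first)
#' @export
pairwiseDistanceSummary <- function(coords, k = 3L) {
    coords <- as.matrix(coords)
    if (nrow(coords) < 2L) stop("need at least 2 cells")
    allPairs <- as.numeric(stats::dist(coords))
    if (nrow(coords) < k + 1L) {
        warning(sprintf(
            "fewer than %d cells: cannot report %d-NN distances",
            k + 1L, k))
        return(list(allPairs = allPairs, knn = NULL))
    }
    nn <- knnNeighbors(coords, k)
    list(allPairs = allPairs, knn = nn$distance)
}

#' Build the direct-contact cell graph
#'
#' For every cell, its `k` nearest neighbors (Euclidean distance, ties
#' broken by ascending cell index) falling under `distanceThreshold`
#' are nominated as direct contacts; the union of all nominations forms
#' the undirected adjacency graph, so an edge exists if either endpoint
#' nominates it. With `distanceThreshold = "auto"` the cutoff is the
#' 97.5th percentile of the pooled k-NN distance distribution, which
#' trims the long tail of isolated cells while keeping nearly all
#' contacts.
#'
#' @param coords numeric matrix of x/y coordinates
#' @param k neighbors per cell (default 3, the direct-contact
#'   convention)
#' @param distanceThreshold positive number, `Inf`, or `"auto"`
#' @return a [CellGraph-class]
#' @examples
#' xy <- cbind(runif(50), runif(50))
#' g <- buildAdjacency(xy)
#' g
#' @export
buildAdjacency <- function(coords, k = 3L, distanceThreshold = "auto") {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    if (n < k + 1L)
        stop(sprintf("need at least %d cells for a %d-NN graph", k + 1L, k))
    nn <- knnNeighbors(coords, k)
    if (identical(distanceThreshold, "auto")) {
        distanceThreshold <- stats::quantile(nn$distance, 0.975,
                                             names = FALSE)
    } else {
        stopifnot(is.numeric(distanceThreshold),
                  length(distanceThreshold) == 1L)
        if (distanceThreshold <= 0)
            stop("distanceThreshold must be positive")
    }
    keep <- nn$distance <= distanceThreshold
    from <- rep(seq_len(n), times = k)[as.vector(keep)]
    to <- as.vector(nn$index)[as.vector(keep)]
    cellGraph(cbind(from, to), nCells = n)
}

#' Split graph edges into train/test sets with sampled negatives
#'
#' Uniformly partitions the observed edges into a training set and a
#' held-out test set, and samples `negRatio` times as many non-edges
#' (uniformly, without replacement, self-pairs excluded) as the test
#' negative set. The defaults reproduce the evaluation protocol of the
#' link-prediction benchmarks: 90/10 split with a negative set 100x the
#' positive one.
#'
#' @param graph a [CellGraph-class] with at least 10 edges
#' @param testFraction fraction of edges held out (default 0.1)
#' @param negRatio size of the negative set relative to the test
#'   positives (default 100); may be 0
#' @param seed integer seed; the split is reproducible from it
#' @return an [EdgeSplit-class]
#' @export
splitEdges <- function(graph, testFraction = 0.1, negRatio = 100,
                       seed = 1L) {
    stopifnot(methods::is(graph, "CellGraph"),
              testFraction >= 0, testFraction < 1, negRatio >= 0)
    e <- edges(graph)
    n <- nCells(graph)
    if (nrow(e) < 10L) stop("need at least 10 edges to split")
    withr::with_seed(as.integer(seed), {
        nTest <- round(testFraction * nrow(e))
        testIdx <- sample.int(nrow(e), nTest)
        testPos <- e[testIdx, , drop = FALSE]
        trainPos <- e[setdiff(seq_len(nrow(e)), testIdx), , drop = FALSE]
        nNeg <- round(negRatio * nTest)
        totalPairs <- n * (n - 1) / 2
        nonEdges <- totalPairs - nrow(e)
        if (nNeg > nonEdges)
            stop(sprintf(
                paste0("requested %d negatives but only %d non-edges ",
                       "exist (maximum feasible ratio %.2f)"),
                nNeg, nonEdges, nonEdges / max(nTest, 1L)))
        testNeg <- if (nNeg > 0) {
            codes <- samplePairCodes(n, nNeg,
                                     excludeCodes = edgeCodes(e, n))
            pairDecode(codes, n)
        } else matrix(integer(0), 0L, 2L,
                      dimnames = list(NULL, c("i", "j")))
        methods::new("EdgeSplit", nCells = n,
                     trainPos = canonicalEdges(trainPos),
                     testPos = canonicalEdges(testPos),
                     testNeg = canonicalEdges(testNeg),
                     negRatio = negRatio)
    })
}

#' Read / write edge lists
#'
#' Edge lists are TSV files with two columns of 0-based cell indices
#' (`cell_i`, `cell_j`), one undirected edge per line. `writeEdgeList()`
#' additionally writes a `cell_id`-labeled variant when identifiers are
#' supplied. `readEdgeList()` lets a user-supplied adjacency bypass
#' [buildAdjacency()].
#'
#' @param path file path
#' @param nCells number of cells in the tissue the edges refer to
#' @return `readEdgeList()`: a [CellGraph-class]
#' @export
readEdgeList <- function(path, nCells) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE)
    cellGraph(cbind(tab$cell_i + 1L, tab$cell_j + 1L), nCells = nCells)
}

#' @rdname readEdgeList
#' @param graph a [CellGraph-class]
#' @param ids optional character vector of cell identifiers
#' @export
writeEdgeList <- function(graph, path, ids = NULL) {
    e <- edges(graph)
    utils::write.table(
        data.frame(cell_i = e[, 1L] - 1L, cell_j = e[, 2L] - 1L),
        path, sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(ids)) {
        utils::write.table(
            data.frame(cell_i = ids[e[, 1L]], cell_j = ids[e[, 2L]]),
            sub("(\\.tsv)?$", ".ids.tsv", path), sep = "\t",
            row.names = FALSE, quote = FALSE)
    }
    invisible(path)
}
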