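#' @include AllClasses.R
NULL

#' @rdname exprMatrix
#' @export
setMethod("exprMatrix", "SpatialCellExperiment", function(x) {
    t(as.matrix(SummarizedExperiment::assay(x, "counts")))
})

#' @rdname spatialCoords
#' @export
setMethod("spatialCoords", "SpatialCellExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    m <- cbind(x = cd$x, y = cd$y)
    rownames(m) <- colnames(x)
    m
})

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "SpatialCellExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("cell_type" %in% colnames(cd)) as.character(cd$cell_type) else NULL
})

#' @rdname nCells
#' @export
setMethod("nCells", "SpatialCellExperiment", function(x) ncol(x))

#' @rdname nCells
#' @export
setMethod("nCells", "CellGraph", function(x) x@nCells)

#' @rdname nGenes
#' @export
setMethod("nGenes", "SpatialCellExperiment", function(x) nrow(x))

#' Gene names of a dataset
#' @param x a `SpatialCellExperiment`
#' @return character vector
#' @export
geneNames <- function(x) rownames(x)

#' Cell identifiers of a dataset
#' @param x a `SpatialCellExperiment`
#' @return character vector
#' @export
cellIds <- function(x) colnames(x)

#' @rdname edges
#' @export
setMethod("edges", "CellGraph", function(x) x@edgeMatrix)

#' @rdname edges
#' @export
setMethod("edges", "ReconstructedNetwork", function(x) {
    as.matrix(x@edgeTable[, c("i", "j")])
})

#' @rdname nEdges
#' @export
setMethod("nEdges", "CellGraph", function(x) nrow(x@edgeMatrix))

#' @rdname nEdges
#' @export
setMethod("nEdges", "ReconstructedNetwork", function(x) nrow(x@edgeTable))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "CellGraph", function(x) {
    n <- x@nCells
    e <- x@edgeMatrix
    Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]),
                         j = c(e[, 2L], e[, 1L]),
                         x = 1, dims = c(n, n))
})

#' @rdname latentMeans
#' @export
setMethod("latentMeans", "LatentEmbedding", function(x) x@mu)

#' @rdname latentMeans
#' @export
setMethod("latentLogSigmas", "LatentEmbedding", function(x) x@logSigma)

#' @rdname latentMeans
#' @export
setMethod("latentSample", "LatentEmbedding", function(x) x@sample)

#' @rdname latentMeans
#' @export
setMethod("latentMeans", "LinkModel", function(x) x@embedding@mu)

#' @rdname trainingLog
#' @export
setMethod("trainingLog", "LinkModel", function(x) x@log)

#' Edge table of a reconstructed network
#' @param x a `ReconstructedNetwork`
#' @return data.frame with probability, distance and labels per edge
#' @export
edgeTable <- function(x) {
    stopifnot(methods::is(x, "ReconstructedNetwork"))
    x@edgeTable
}

#' True planted edges of a synthetic tissue
#' @param x a `SyntheticTruth`
#' @return two-column integer matrix
#' @export
trueEdges <- function(x) {
    stopifnot(methods::is(x, "SyntheticTruth"))
    x@trueEdges
}

#' Informative gene indices of a synthetic tissue
#' @param x a `SyntheticTruth`
#' @return integer vector
#' @export
informativeGenes <- function(x) {
    stopifnot(methods::is(x, "SyntheticTruth"))
    x@informativeGenes
}

# ---- show methods ---------------------------------------------------------

setMethod("show", "SpatialCellExperiment", function(object) {
    cat(sprintf("SpatialCellExperiment: %d cells x %d genes\n",
                ncol(object), nrow(object)))
    xy <- spatialCoords(object)
    cat(sprintf("  field: x [%.3g, %.3g], y [%.3g, %.3g]\n",
                min(xy[, 1L]), max(xy[, 1L]), min(xy[, 2L]), max(xy[, 2L])))
    ct <- cellTypes(object)
    if (!is.null(ct))
        cat(sprintf("  cell types: %s\n",
                    paste(names(sort(table(ct), decreasing = TRUE)),
                          collapse = ", ")))
})

setMethod("show", "CellGraph", function(object) {
    cat(sprintf("CellGraph: %d cells, %d undirected edges (mean degree %.2f)\n",
                object@nCells, nrow(object@edgeMatrix),
                if (object@nCells)
                    2 * nrow(object@edgeMatrix) / object@nCells else 0))
})

setMethod("show", "EdgeSplit", function(object) {
    cat(sprintf(
        "EdgeSplit: %d train / %d test positives, %d test negatives (%gx)\n",
        nrow(object@trainPos), nrow(object@testPos), nrow(object@testNeg),
        object@negRatio))
})

setMethod("show", "LatentEmbedding", function(object) {
    cat(sprintf("LatentEmbedding: %d cells x %d latent dimensions\n",
                nrow(object@mu), ncol(object@mu)))
})

setMethod("show", "LinkModel", function(object) {
    cfg <- object@config
    cat(sprintf(
        "LinkModel: %d -> %d -> %d encoder, %d epochs trained\n",
        nrow(object@params$W0), cfg$hidden, cfg$latent, nrow(object@log)))
    if (nrow(object@log)) {
        last <- object@log[nrow(object@log), ]
        cat(sprintf("  final loss %.4f, test AUROC %.3f\n",
                    last$loss, last$test_auroc))
    }
})

setMethod("show", "ReconstructedNetwork", function(object) {
    et <- object@edgeTable
    cat(sprintf(
        "ReconstructedNetwork: %d edges at threshold %.4g (%d cells)\n",
        nrow(et), object@threshold, object@nCells))
    if (!is.na(object@distalCutoff))
        cat(sprintf("  %d distal / %d proximal (distance cutoff %.4g)\n",
                    sum(et$is_distal), sum(!et$is_distal),
                    object@distalCutoff))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: %d planted edges, %d informative genes\n",
        nrow(object@trueEdges), length(object@informativeGenes)))
})
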