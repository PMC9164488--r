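#' @include AllGenerics.R
NULL

# ---- SpatialCellExperiment ------------------------------------------------

#' SpatialCellExperiment: expression + spatial coordinates
#'
#' An S4 container for a single-cell spatial transcriptome section,
#' extending [SingleCellExperiment::SingleCellExperiment]. Genes are
#' stored in rows of the `counts` assay (the Bioconductor convention);
#' per-cell x/y coordinates and the optional cell-type annotation live
#' in `colData`. Use [exprMatrix()] to obtain the cells x genes
#' orientation consumed by the model.
#'
#' @slot ... inherited from `SingleCellExperiment`
#' @seealso [readSpatialDataset()], [simulateTissue()], [cropField()]
#' @export
setClass("SpatialCellExperiment", contains = "SingleCellExperiment")

setValidity("SpatialCellExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is missing")
    x <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(x)))
        msg <- c(msg, "expression contains non-finite entries")
    else if (any(x < 0)) {
        bad <- which(x < 0, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf(
            "negative expression at gene %d, cell %d", bad[1L], bad[2L]))
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("x", "y") %in% colnames(cd)))
        msg <- c(msg, "colData must contain spatial coordinates 'x' and 'y'")
    else if (any(!is.finite(cd$x)) || any(!is.finite(cd$y)))
        msg <- c(msg, "spatial coordinates contain non-finite values")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene names are not unique")
    if (length(msg)) msg else TRUE
})

#' Construct a SpatialCellExperiment
#'
#' @param expression numeric matrix, cells x genes, non-negative and
#'   finite
#' @param coordinates numeric matrix or data.frame with two columns
#'   (x, y), one row per cell, in the length units of the source dataset
#' @param cellTypes optional character/factor vector of per-cell type
#'   labels
#' @param geneNames,cellIds optional dimension names; default to the
#'   dimnames of `expression` or generated `gene1..`/`cell1..` labels
#' @return a validated [SpatialCellExperiment-class] object
#' @examples
#' expr <- matrix(rpois(6, 2), nrow = 3,
#'                dimnames = list(NULL, c("g1", "g2")))
#' sce <- SpatialCellExperiment(expr, cbind(x = 1:3, y = 0))
#' nCells(sce)
#' @export
SpatialCellExperiment <- function(expression, coordinates,
                                  cellTypes = NULL,
                                  geneNames = colnames(expression),
                                  cellIds = rownames(expression)) {
    expression <- as.matrix(expression)
    coordinates <- as.matrix(coordinates)
    storage.mode(coordinates) <- "double"
    if (ncol(coordinates) != 2L)
        stop("'coordinates' must have exactly two columns (x, y)")
    if (nrow(coordinates) != nrow(expression))
        stop(sprintf(
            "coordinate rows (%d) do not match expression rows (%d)",
            nrow(coordinates), nrow(expression)))
    if (is.null(geneNames))
        geneNames <- paste0("gene", seq_len(ncol(expression)))
    if (is.null(cellIds))
        cellIds <- paste0("cell", seq_len(nrow(expression)))
    if (!is.null(cellTypes)) {
        if (length(cellTypes) != nrow(expression))
            stop(sprintf(
                "cellTypes length (%d) does not match number of cells (%d)",
                length(cellTypes), nrow(expression)))
        cellTypes <- as.character(cellTypes)
    }
    cd <- S4Vectors::DataFrame(x = coordinates[, 1L], y = coordinates[, 2L],
                               row.names = cellIds)
    if (!is.null(cellTypes)) cd$cell_type <- cellTypes
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = t(expression)),
        colData = cd)
    rownames(sce) <- geneNames
    methods::new("SpatialCellExperiment", sce)
}

# ---- CellGraph ------------------------------------------------------------

#' CellGraph: proximity-derived cell adjacency
#'
#' A symmetric, self-loop-free undirected graph over cells, stored as a
#' two-column integer edge matrix with `i < j`. This is the observed
#' (noisy, incomplete) interaction set the model trains on.
#'
#' @slot nCells integer, number of cells (nodes)
#' @slot edgeMatrix integer matrix, columns `i`, `j`, 1-based, `i < j`
#' @seealso [buildAdjacency()], [cellGraph()], [adjacencyMatrix()]
#' @export
setClass("CellGraph",
         representation(nCells = "integer", edgeMatrix = "matrix"))

setValidity("CellGraph", function(object) {
    e <- object@edgeMatrix
    n <- object@nCells
    if (length(n) != 1L || is.na(n) || n < 0L) return("invalid nCells")
    if (ncol(e) != 2L) return("edgeMatrix must have two columns")
    if (nrow(e)) {
        if (!is.integer(e)) return("edgeMatrix must be integer")
        if (any(e < 1L) || any(e > n)) return("edge index out of range")
        if (any(e[, 1L] >= e[, 2L]))
            return("edges must satisfy i < j (no self-edges)")
        if (anyDuplicated(e)) return("duplicate edges")
    }
    TRUE
})

#' Create a CellGraph from an edge matrix
#'
#' Edges may be given in any order and orientation; they are
#' canonicalized to `i < j`, deduplicated, and validated. Self-pairs are
#' rejected.
#'
#' @param edgeMatrix two-column matrix of 1-based cell indices (may be
#'   empty)
#' @param nCells number of cells in the tissue
#' @return a [CellGraph-class]
#' @examples
#' g <- cellGraph(rbind(c(2, 1), c(1, 3)), nCells = 4)
#' nEdges(g)
#' @export
cellGraph <- function(edgeMatrix, nCells) {
    edgeMatrix <- matrix(as.integer(edgeMatrix), ncol = 2L)
    if (nrow(edgeMatrix) && any(edgeMatrix[, 1L] == edgeMatrix[, 2L]))
        stop("self-edges are not allowed")
    e <- canonicalEdges(edgeMatrix)
    methods::new("CellGraph", nCells = as.integer(nCells), edgeMatrix = e)
}

# canonical form: i < j, sorted, unique
canonicalEdges <- function(e) {
    e <- matrix(as.integer(e), ncol = 2L)
    if (!nrow(e)) {
        colnames(e) <- c("i", "j")
        return(e)
    }
    swap <- e[, 1L] > e[, 2L]
    e[swap, ] <- e[swap, c(2L, 1L)]
    e <- unique(e)
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
    colnames(e) <- c("i", "j")
    e
}

# ---- EdgeSplit ------------------------------------------------------------

#' EdgeSplit: train/test partition with sampled negatives
#'
#' Produced by [splitEdges()]. `trainPos` and `testPos` partition the
#' observed edges; `testNeg` holds sampled non-edges used as the
#' evaluation negative set.
#'
#' @slot nCells integer
#' @slot trainPos,testPos,testNeg two-column integer edge matrices
#' @slot negRatio numeric, requested size of `testNeg` relative to
#'   `testPos`
#' @export
setClass("EdgeSplit",
         representation(nCells = "integer", trainPos = "matrix",
                        testPos = "matrix", testNeg = "matrix",
                        negRatio = "numeric"))

setValidity("EdgeSplit", function(object) {
    allp <- rbind(object@trainPos, object@testPos)
    if (nrow(allp) && anyDuplicated(allp))
        return("trainPos and testPos overlap")
    both <- rbind(allp, object@testNeg)
    if (nrow(both) && anyDuplicated(both))
        return("testNeg intersects observed edges")
    TRUE
})

# ---- LatentEmbedding ------------------------------------------------------

#' LatentEmbedding: variational posterior over the latent space
#'
#' Per-cell Gaussian posterior parameters produced by the encoder:
#' means, log standard deviations, and the reparameterized sample
#' `H = mu + exp(logSigma) * eps`. In eval mode the sample equals the
#' mean.
#'
#' @slot mu,logSigma,sample numeric matrices, cells x latent dims
#' @export
setClass("LatentEmbedding",
         representation(mu = "matrix", logSigma = "matrix",
                        sample = "matrix"))

setValidity("LatentEmbedding", function(object) {
    if (!all(dim(object@mu) == dim(object@logSigma)) ||
        !all(dim(object@mu) == dim(object@sample)))
        return("mu, logSigma and sample must share dimensions")
    if (any(!is.finite(object@mu)) || any(!is.finite(object@logSigma)))
        return("non-finite posterior parameters")
    TRUE
})

# ---- LinkModel ------------------------------------------------------------

#' LinkModel: a trained adversarial variational graph autoencoder
#'
#' Holds the model configuration, the learned weights of the
#' graph-convolutional encoder and of the adversarial discriminator,
#' the latent embedding of the training dataset, and the per-epoch
#' training log.
#'
#' @slot config list, see [linkModelConfig()]
#' @slot params list of weight matrices (`W0`, `W1mu`, `W1sig`,
#'   discriminator `Wd1`/`bd1`/`Wd2`/`bd2`/`wd3`/`bd3`)
#' @slot embedding [LatentEmbedding-class] of the training cells
#' @slot log data.frame, one row per epoch
#' @slot featureInfo list describing the feature preprocessing applied
#'   before encoding (so that downstream rescoring reproduces it)
#' @export
setClass("LinkModel",
         representation(config = "list", params = "list",
                        embedding = "LatentEmbedding", log = "data.frame",
                        featureInfo = "list"))

# ---- ReconstructedNetwork -------------------------------------------------

#' ReconstructedNetwork: thresholded decoder output
#'
#' The completed interaction network: all cell pairs whose decoded
#' probability reaches the selected threshold, annotated with the
#' Euclidean distance between the endpoints, a proximal/distal label,
#' and membership in the original adjacency graph.
#'
#' @slot edgeTable data.frame with columns `i`, `j`, `probability`,
#'   `distance`, `is_distal`, `in_original`
#' @slot threshold numeric, probability cutoff used for assembly
#' @slot distalCutoff numeric, distance above which an edge is distal
#'   (`NA` until [classifyDistal()] is applied)
#' @slot nCells integer
#' @export
setClass("ReconstructedNetwork",
         representation(edgeTable = "data.frame", threshold = "numeric",
                        distalCutoff = "numeric", nCells = "integer"))

setValidity("ReconstructedNetwork", function(object) {
    et <- object@edgeTable
    need <- c("i", "j", "probability", "distance", "is_distal",
              "in_original")
    if (!all(need %in% colnames(et)))
        return(paste("edgeTable must contain",
                     paste(need, collapse = ", ")))
    if (nrow(et) && any(et$probability < object@threshold))
        return("edge below the assembly threshold")
    TRUE
})

# ---- SyntheticTruth -------------------------------------------------------

#' SyntheticTruth: generator ground truth
#'
#' Returned by [simulateTissue()] alongside the dataset: the planted
#' interaction edges, the indices of the informative genes, and the
#' full set of generator parameters (including the seed), so that
#' recovery can be scored exactly.
#'
#' @slot trueEdges two-column integer matrix, `i < j`
#' @slot informativeGenes integer vector of gene indices
#' @slot generatorParams list of all sampling parameters and the seed
#' @export
setClass("SyntheticTruth",
         representation(trueEdges = "matrix",
                        informativeGenes = "integer",
                        generatorParams = "list"))

setValidity("SyntheticTruth", function(object) {
    e <- object@trueEdges
    if (nrow(e) && any(e[, 1L] >= e[, 2L]))
        return("trueEdges must satisfy i < j")
    ng <- object@generatorParams$n_genes
    if (!is.null(ng) && length(object@informativeGenes) &&
        (any(object@informativeGenes < 1L) ||
         any(object@informativeGenes > ng)))
        return("informative gene index out of range")
    TRUE
})
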