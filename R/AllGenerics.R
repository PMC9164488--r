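#' @include spanet-package.R
NULL

#' Expression matrix accessor
#'
#' Returns the cells x genes expression matrix of a
#' [SpatialCellExperiment]. Rows are cells, columns are genes, matching
#' the on-disk orientation of spatial transcriptome portals (and the
#' orientation consumed by the encoder).
#'
#' @param x a `SpatialCellExperiment`
#' @return numeric matrix, cells in rows
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' Spatial coordinates accessor
#'
#' @param x a `SpatialCellExperiment`
#' @return numeric matrix with columns `x`, `y`, one row per cell
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' Cell-type annotation accessor
#'
#' @param x a `SpatialCellExperiment`
#' @return character vector of per-cell type labels, or `NULL` when the
#'   dataset carries no annotation
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' Number of cells
#' @param x a `SpatialCellExperiment` or `CellGraph`
#' @return integer
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Number of genes
#' @param x a `SpatialCellExperiment`
#' @return integer
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' Edge list accessor
#'
#' Edges of a [CellGraph] or [ReconstructedNetwork] as a two-column
#' integer matrix of 1-based cell indices with `i < j` (each undirected
#' edge stored once).
#'
#' @param x a `CellGraph` or `ReconstructedNetwork`
#' @return integer matrix with columns `i`, `j`
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Number of edges
#' @param x a `CellGraph` or `ReconstructedNetwork`
#' @return integer
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' Binary adjacency matrix
#'
#' @param x a `CellGraph`
#' @return sparse symmetric `dgCMatrix` with zero diagonal
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Latent embedding accessors
#'
#' `latentMeans()` and `latentLogSigmas()` return the per-cell Gaussian
#' posterior parameters; `latentSample()` returns the reparameterized
#' sample drawn during the last training epoch.
#'
#' @param x a `LatentEmbedding` or `LinkModel`
#' @return numeric matrix, cells x latent dimensions
#' @export
setGeneric("latentMeans", function(x) standardGeneric("latentMeans"))

#' @rdname latentMeans
#' @export
setGeneric("latentLogSigmas", function(x) standardGeneric("latentLogSigmas"))

#' @rdname latentMeans
#' @export
setGeneric("latentSample", function(x) standardGeneric("latentSample"))

#' Training log accessor
#' @param x a `LinkModel`
#' @return data.frame with one row per epoch
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))
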