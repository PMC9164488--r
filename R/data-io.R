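#' @include AllClasses.R
NULL

#' Read a spatial transcriptome dataset from disk
#'
#' Reads an expression matrix, per-cell spatial coordinates, and an
#' optional cell-type annotation, and assembles a validated
#' [SpatialCellExperiment-class]. Three on-disk layouts are supported:
#'
#' * `dense_csv` / `dense_tsv`: cells x genes table, first row gene
#'   names, first column cell identifiers;
#' * `mtx_triplet`: MatrixMarket coordinate file (cells x genes) with
#'   companion row-name (`<stem>.rows.txt`) and column-name
#'   (`<stem>.cols.txt`) files.
#'
#' The coordinate file must contain columns `cell_id`, `x`, `y`; the
#' annotation file `cell_id`, `cell_type`. When all files carry cell
#' identifiers, rows are aligned by identifier; otherwise alignment is
#' positional. Dimension mismatches and negative expression values are
#' rejected with the offending file / entry named.
#'
#' @param expressionPath path to the expression matrix
#' @param coordinatesPath path to the coordinate table
#' @param annotationPath optional path to the cell-type table
#' @param format one of `"dense_csv"`, `"dense_tsv"`, `"mtx_triplet"`
#' @return a [SpatialCellExperiment-class]
#' @seealso [writeSpatialDataset()] for the inverse operation
#' @export
readSpatialDataset <- function(expressionPath, coordinatesPath,
                               annotationPath = NULL,
                               format = c("dense_csv", "dense_tsv",
                                          "mtx_triplet")) {
    format <- match.arg(format)
    for (p in c(expressionPath, coordinatesPath, annotationPath))
        if (!file.exists(p)) stop("file not found: ", p)

    if (format == "mtx_triplet") {
        m <- as.matrix(Matrix::readMM(expressionPath))
        stem <- sub("\\.mtx$", "", expressionPath)
        rowsFile <- paste0(stem, ".rows.txt")
        colsFile <- paste0(stem, ".cols.txt")
        ids <- if (file.exists(rowsFile)) readLines(rowsFile) else NULL
        gn <- if (file.exists(colsFile)) readLines(colsFile) else NULL
        if (!is.null(ids) && length(ids) != nrow(m))
            stop(sprintf("row-name file %s has %d entries for %d cells",
                         rowsFile, length(ids), nrow(m)))
        if (!is.null(gn) && length(gn) != ncol(m))
            stop(sprintf("column-name file %s has %d entries for %d genes",
                         colsFile, length(gn), ncol(m)))
        rownames(m) <- ids
        colnames(m) <- gn
        expr <- m
    } else {
        sep <- if (format == "dense_csv") "," else "\t"
        tab <- utils::read.table(expressionPath, sep = sep, header = TRUE,
                                 row.names = 1L, check.names = FALSE)
        expr <- as.matrix(tab)
    }
    if (any(expr < 0, na.rm = TRUE)) {
        bad <- which(expr < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "negative expression value at cell %d, gene %d in %s",
            bad[1L], bad[2L], expressionPath))
    }

    coords <- readIdTable(coordinatesPath, c("x", "y"))
    ann <- if (!is.null(annotationPath))
        readIdTable(annotationPath, "cell_type") else NULL

    if (nrow(coords) != nrow(expr))
        stop(sprintf(
            "alignment error: %s has %d rows but expression has %d cells",
            coordinatesPath, nrow(coords), nrow(expr)))
    if (!is.null(ann) && nrow(ann) != nrow(expr))
        stop(sprintf(
            "alignment error: %s has %d rows but expression has %d cells",
            annotationPath, nrow(ann), nrow(expr)))

    ids <- rownames(expr)
    haveIds <- !is.null(ids) && !is.null(coords$cell_id) &&
        all(ids %in% coords$cell_id) &&
        (is.null(ann) || (!is.null(ann$cell_id) &&
                          all(ids %in% ann$cell_id)))
    if (haveIds) {
        coords <- coords[match(ids, coords$cell_id), , drop = FALSE]
        if (!is.null(ann))
            ann <- ann[match(ids, ann$cell_id), , drop = FALSE]
    }
    SpatialCellExperiment(
        expression = expr,
        coordinates = cbind(coords$x, coords$y),
        cellTypes = if (!is.null(ann)) ann$cell_type else NULL,
        geneNames = colnames(expr),
        cellIds = ids)
}

# coordinate/annotation tables: cell_id + named columns; tolerate a
# missing cell_id column (positional alignment)
readIdTable <- function(path, needed) {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
    missing <- setdiff(needed, colnames(tab))
    if (length(missing))
        stop(sprintf("%s lacks required column(s): %s", path,
                     paste(missing, collapse = ", ")))
    tab
}

#' Write a spatial transcriptome dataset to disk
#'
#' Inverse of [readSpatialDataset()]: writes the expression matrix, the
#' coordinate table and (when present) the annotation table into `dir`.
#' Dense formats round-trip values at full precision.
#'
#' @param ds a [SpatialCellExperiment-class]
#' @param dir output directory (created if needed)
#' @param format as in [readSpatialDataset()]
#' @return invisibly, the paths written (named list)
#' @export
writeSpatialDataset <- function(ds, dir,
                                format = c("dense_csv", "dense_tsv",
                                           "mtx_triplet")) {
    format <- match.arg(format)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    expr <- exprMatrix(ds)
    coords <- spatialCoords(ds)
    ext <- switch(format, dense_csv = "csv", dense_tsv = "tsv",
                  mtx_triplet = "mtx")
    exprPath <- file.path(dir, paste0("expression.", ext))
    if (format == "mtx_triplet") {
        Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), exprPath)
        writeLines(cellIds(ds), file.path(dir, "expression.rows.txt"))
        writeLines(geneNames(ds), file.path(dir, "expression.cols.txt"))
    } else {
        sep <- if (format == "dense_csv") "," else "\t"
        tab <- data.frame(cell_id = cellIds(ds), expr,
                          check.names = FALSE)
        utils::write.table(tab, exprPath, sep = sep, row.names = FALSE,
                           quote = FALSE)
    }
    coordPath <- file.path(dir, "coordinates.csv")
    utils::write.table(
        data.frame(cell_id = cellIds(ds), x = coords[, 1L],
                   y = coords[, 2L]),
        coordPath, sep = ",", row.names = FALSE, quote = FALSE)
    out <- list(expression = exprPath, coordinates = coordPath)
    ct <- cellTypes(ds)
    if (!is.null(ct)) {
        annPath <- file.path(dir, "annotation.csv")
        utils::write.table(
            data.frame(cell_id = cellIds(ds), cell_type = ct),
            annPath, sep = ",", row.names = FALSE, quote = FALSE)
        out$annotation <- annPath
    }
    invisible(out)
}

#' Crop a rectangular field from a tissue section
#'
#' Keeps the cells whose coordinates fall inside the closed intervals
#' `xRange` and `yRange` (boundary points are retained). Genes are
#' unchanged. Mirrors the field selections applied to high-definition
#' spatial datasets and drives the tissue-cropping benchmark.
#'
#' @param ds a [SpatialCellExperiment-class]
#' @param xRange,yRange numeric length-2 vectors, `min <= max`
#' @return the cropped [SpatialCellExperiment-class]
#' @export
cropField <- function(ds, xRange, yRange) {
    stopifnot(length(xRange) == 2L, length(yRange) == 2L,
              all(is.finite(c(xRange, yRange))),
              xRange[1L] <= xRange[2L], yRange[1L] <= yRange[2L])
    xy <- spatialCoords(ds)
    keep <- xy[, 1L] >= xRange[1L] & xy[, 1L] <= xRange[2L] &
        xy[, 2L] >= yRange[1L] & xy[, 2L] <= yRange[2L]
    if (!any(keep))
        stop("crop produced an empty dataset (no cells in range)")
    SpatialCellExperiment(
        expression = exprMatrix(ds)[keep, , drop = FALSE],
        coordinates = xy[keep, , drop = FALSE],
        cellTypes = cellTypes(ds)[keep],
        geneNames = geneNames(ds),
        cellIds = cellIds(ds)[keep])
}
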