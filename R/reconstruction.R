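#' @include AllClasses.R
NULL

#' Select the assembly probability threshold
#'
#' Sweeps the unique predicted scores of the held-out test instances
#' and returns the threshold maximizing accuracy on
#' `test_pos + test_neg` (a pair is predicted interacting when its
#' score is `>=` the threshold). Ties are broken toward the larger
#' threshold. With the 100x negative convention plain accuracy is
#' dominated by negatives; `balanced = TRUE` optimizes the mean of
#' sensitivity and specificity instead.
#'
#' @param probs probability matrix from [decodeLatent()]
#' @param split an [EdgeSplit-class] with non-empty test sets
#' @param balanced optimize balanced accuracy instead of plain accuracy
#' @return the selected threshold; if all scores are identical, that
#'   score is returned with a warning
#' @export
selectThreshold <- function(probs, split, balanced = FALSE) {
    sp <- probs[split@testPos]
    sn <- probs[split@testNeg]
    if (!length(sp) || !length(sn)) stop("test sets must be non-empty")
    cand <- sort(unique(c(sp, sn)))
    if (length(cand) == 1L) {
        warning("all test scores identical; threshold is degenerate")
        return(cand)
    }
    acc <- vapply(cand, function(t) {
        tpr <- mean(sp >= t); tnr <- mean(sn < t)
        if (balanced) (tpr + tnr) / 2
        else (tpr * length(sp) + tnr * length(sn)) /
            (length(sp) + length(sn))
    }, numeric(1))
    max(cand[acc == max(acc)])
}

#' Assemble the reconstructed interaction network
#'
#' Collects every unordered cell pair whose decoded probability is at
#' or above the threshold (the diagonal is excluded), annotating each
#' edge with the Euclidean distance between its endpoints and, when the
#' original adjacency graph is supplied, with membership in it. All
#' pairs are scored uniformly; original-adjacency membership is an
#' annotation, not a shortcut.
#'
#' @param probs probability matrix from [decodeLatent()]
#' @param threshold probability cutoff in (0, 1)
#' @param coords per-cell coordinate matrix
#' @param graph optional original [CellGraph-class]
#' @return a [ReconstructedNetwork-class]
#' @export
assembleNetwork <- function(probs, threshold, coords, graph = NULL) {
    stopifnot(threshold > 0, threshold <= 1)
    n <- nrow(probs)
    up <- which(upper.tri(probs) & probs >= threshold, arr.ind = TRUE)
    e <- cbind(i = up[, 1L], j = up[, 2L])
    inOrig <- if (!is.null(graph) && nrow(e))
        edgeCodes(e, n) %in% edgeCodes(edges(graph), n)
    else rep(NA, nrow(e))
    et <- data.frame(
        i = as.integer(e[, 1L]), j = as.integer(e[, 2L]),
        probability = probs[cbind(e[, 1L], e[, 2L])],
        distance = edgeLengths(e, coords),
        is_distal = logical(nrow(e)),
        in_original = inOrig)
    methods::new("ReconstructedNetwork", edgeTable = et,
                 threshold = threshold, distalCutoff = NA_real_,
                 nCells = as.integer(n))
}

#' Classify edges as proximal or distal
#'
#' Labels reconstructed edges whose endpoint distance exceeds the
#' cutoff as distal. With `cutoff = "auto"` the cutoff is the 95th
#' percentile of the edge-length distribution of the ORIGINAL
#' proximity graph -- "distal" meaning beyond the direct-contact
#' regime that the adjacency construction encodes -- which requires
#' `referenceDistances` (e.g. `edgeLengths(edges(g), coords)` of the
#' contact graph).
#'
#' @param network a [ReconstructedNetwork-class]
#' @param cutoff positive number or `"auto"`
#' @param referenceDistances numeric vector of original contact-edge
#'   lengths (needed for `"auto"`)
#' @return the network with its distal/proximal partition filled in
#' @export
classifyDistal <- function(network, cutoff = "auto",
                           referenceDistances = NULL) {
    if (identical(cutoff, "auto")) {
        if (is.null(referenceDistances))
            stop("'auto' cutoff needs referenceDistances from the ",
                 "original contact graph")
        cutoff <- stats::quantile(referenceDistances, 0.95,
                                  names = FALSE)
    }
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
    network@edgeTable$is_distal <- network@edgeTable$distance > cutoff
    network@distalCutoff <- as.numeric(cutoff)
    network
}

#' Correlation between predicted probability and distance
#'
#' Spearman correlation between the pairwise Euclidean distance and the
#' decoded interaction probability over all off-diagonal pairs, plus
#' the per-pair table behind it.
#'
#' @param probs probability matrix from [decodeLatent()]
#' @param coords per-cell coordinate matrix
#' @return list with `correlation` (Spearman rho) and `table`
#'   (data.frame `i`, `j`, `distance`, `probability`, n(n-1)/2 rows)
#' @export
distanceProbabilityCorrelation <- function(probs, coords) {
    n <- nrow(probs)
    up <- which(upper.tri(probs), arr.ind = TRUE)
    tab <- data.frame(
        i = as.integer(up[, 1L]), j = as.integer(up[, 2L]),
        distance = edgeLengths(up, coords),
        probability = probs[up])
    list(correlation = stats::cor(tab$distance, tab$probability,
                                  method = "spearman"),
         table = tab)
}

#' Export a reconstructed network as TSV
#'
#' Columns: `cell_i`, `cell_j` (0-based), `probability`, `distance`,
#' `is_distal`, `is_in_original_adjacency`.
#'
#' @param network a [ReconstructedNetwork-class]
#' @param path output file
#' @export
writeNetwork <- function(network, path) {
    et <- network@edgeTable
    utils::write.table(
        data.frame(cell_i = et$i - 1L, cell_j = et$j - 1L,
                   probability = et$probability,
                   distance = et$distance, is_distal = et$is_distal,
                   is_in_original_adjacency = et$in_original),
        path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}
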