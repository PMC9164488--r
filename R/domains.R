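#' @include AllClasses.R vgae-train.R
NULL

# Calinski-Harabasz index of a k-means fit: ratio of between- to
# within-cluster dispersion, df-corrected
chScore <- function(fit, n) {
    k <- length(fit$size)
    (fit$betweenss / (k - 1)) / (fit$tot.withinss / (n - k))
}

#' Cluster cells on the latent embedding
#'
#' K-means over the first `latentDim` latent dimensions, run for every
#' candidate cluster number in `kRange` with multiple seeded restarts;
#' the Calinski-Harabasz score picks the final `k`. The intended
#' workflow trains a model whose latent width equals `latentDim`
#' (see [findSpatialDomains()]) rather than truncating a wide
#' embedding; truncation of a wider matrix is supported but secondary.
#'
#' @param H latent matrix (cells x dims), [LatentEmbedding-class] or
#'   [LinkModel-class]
#' @param kRange candidate cluster numbers (default 2:12)
#' @param latentDim number of leading latent dimensions to use
#'   (default 10)
#' @param seed integer seed for the k-means restarts
#' @param nStart random restarts per k (default 20, best inertia kept)
#' @return a list of class `DomainAssignment`: `cluster` (1-based
#'   integer per cell), `k`, `chScores` (named by candidate k, `NA`
#'   when skipped), `latentDim`, `skipped`
#' @export
clusterLatent <- function(H, kRange = 2:12, latentDim = 10L, seed = 1L,
                          nStart = 20L) {
    if (methods::is(H, "LinkModel")) H <- latentMeans(H)
    if (methods::is(H, "LatentEmbedding")) H <- latentMeans(H)
    latentDim <- as.integer(min(latentDim, ncol(H)))
    Z <- H[, seq_len(latentDim), drop = FALSE]
    n <- nrow(Z)
    nDistinct <- nrow(unique(Z))
    if (nDistinct < 2L)
        stop("all cells identical in the latent space; no valid k")
    kRange <- kRange[kRange >= 2L & kRange <= n - 1L]
    if (!length(kRange)) stop("kRange contains no feasible k")
    fits <- list(); ch <- setNames(rep(NA_real_, length(kRange)),
                                   kRange)
    skipped <- integer(0)
    withr::with_seed(as.integer(seed), {
        for (ki in seq_along(kRange)) {
            k <- kRange[ki]
            if (k > nDistinct) { skipped <- c(skipped, k); next }
            fit <- tryCatch(
                stats::kmeans(Z, centers = k, nstart = nStart,
                              iter.max = 100L),
                error = function(e) NULL)
            if (is.null(fit)) { skipped <- c(skipped, k); next }
            fits[[ki]] <- fit
            ch[ki] <- chScore(fit, n)
        }
    })
    if (all(is.na(ch))) stop("no candidate k produced a clustering")
    best <- which.max(ch)
    structure(list(cluster = fits[[best]]$cluster,
                   k = kRange[best], chScores = ch,
                   latentDim = latentDim, skipped = skipped),
              class = "DomainAssignment")
}

#' @export
print.DomainAssignment <- function(x, ...) {
    cat(sprintf(
        "DomainAssignment: %d cells in %d domains (CH-selected from k = %s)\n",
        length(x$cluster), x$k,
        paste(range(as.integer(names(x$chScores))), collapse = "-")))
    invisible(x)
}

#' Detect spatial domains from scratch
#'
#' Convenience wrapper for the domain workflow: trains a model with a
#' narrow latent space (width 10 by default, the width used for
#' clustering), then clusters the cells with [clusterLatent()].
#'
#' @param ds a [SpatialCellExperiment-class]
#' @param graph optional [CellGraph-class]; built from the coordinates
#'   when missing
#' @param config a [linkModelConfig()]; its `latent` sets the
#'   clustering dimensionality
#' @param kRange candidate cluster numbers
#' @return list with `assignment` (`DomainAssignment`), `model`
#'   ([LinkModel-class]) and `split` ([EdgeSplit-class])
#' @export
findSpatialDomains <- function(ds, graph = NULL,
                               config = linkModelConfig(latent = 10L),
                               kRange = 2:12) {
    if (is.null(graph)) graph <- buildAdjacency(spatialCoords(ds))
    split <- splitEdges(graph, seed = config$seed)
    model <- trainLinkModel(ds, split, config)
    assignment <- clusterLatent(model, kRange = kRange,
                                latentDim = config$latent,
                                seed = config$seed)
    list(assignment = assignment, model = model, split = split)
}

#' Domain-specific marker genes
#'
#' For each domain (optionally restricted to one cell type), tests
#' every gene for upregulation with one-sided Mann-Whitney U tests,
#' one-versus-rest and one-versus-one against every other domain. A
#' gene is domain-specific when the one-vs-rest p-value and ALL
#' one-vs-one p-values fall below `alpha`. Reported alongside is the
#' median of the gene's z-score (computed gene-wise across the
#' filtered cells) within the domain. Domains with fewer than
#' `minCells` cells are excluded (recorded in the `"excluded"`
#' attribute); constant genes yield p = 1 by convention.
#'
#' @param ds a [SpatialCellExperiment-class]
#' @param assignment a `DomainAssignment` (or integer vector of domain
#'   labels per cell)
#' @param cellTypeFilter optional single cell type to restrict to
#' @param alpha significance level for both test families (default
#'   0.01, uncorrected)
#' @param minCells minimum cells per tested domain (default 3)
#' @return data.frame `domain`, `gene`, `median_z`, `p_one_vs_rest`,
#'   `p_one_vs_one_max`, `is_domain_specific`
#' @export
domainMarkerGenes <- function(ds, assignment, cellTypeFilter = NULL,
                              alpha = 0.01, minCells = 3L) {
    cl <- if (inherits(assignment, "DomainAssignment"))
        assignment$cluster else as.integer(assignment)
    stopifnot(length(cl) == nCells(ds))
    keep <- rep(TRUE, nCells(ds))
    if (!is.null(cellTypeFilter)) {
        ct <- cellTypes(ds)
        if (is.null(ct)) stop("dataset carries no cell-type annotation")
        keep <- ct == cellTypeFilter
    }
    X <- exprMatrix(ds)[keep, , drop = FALSE]
    cl <- cl[keep]
    sizes <- table(cl)
    domains <- as.integer(names(sizes)[sizes >= minCells])
    excluded <- as.integer(names(sizes)[sizes < minCells])
    if (length(domains) < 2L)
        stop("need at least two domains with >= minCells cells")

    Z <- scale(X)
    Z[, attr(Z, "scaled:scale") == 0] <- 0

    oneSidedU <- function(a, b) {
        if (length(unique(c(a, b))) == 1L) return(1)
        stats::wilcox.test(a, b, alternative = "greater",
                           exact = FALSE)$p.value
    }

    rows <- lapply(domains, function(d) {
        inD <- cl == d
        pOvr <- numeric(ncol(X)); pOvoMax <- numeric(ncol(X))
        medZ <- numeric(ncol(X))
        for (g in seq_len(ncol(X))) {
            a <- X[inD, g]
            pOvr[g] <- oneSidedU(a, X[!inD & cl %in% domains, g])
            pOvoMax[g] <- max(vapply(
                setdiff(domains, d),
                function(d2) oneSidedU(a, X[cl == d2, g]),
                numeric(1)))
            medZ[g] <- stats::median(Z[inD, g])
        }
        data.frame(domain = d, gene = geneNames(ds),
                   median_z = medZ, p_one_vs_rest = pOvr,
                   p_one_vs_one_max = pOvoMax,
                   is_domain_specific = pOvr < alpha & pOvoMax < alpha)
    })
    out <- do.call(rbind, rows)
    if (length(excluded)) attr(out, "excluded") <- excluded
    rownames(out) <- NULL
    out
}
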