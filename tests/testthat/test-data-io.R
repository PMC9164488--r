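test_that("dense formats round-trip at full precision and align by cell id", {
    tiny <- tinyTissue()
    ds <- tiny$ds
    for (fmt in c("dense_csv", "dense_tsv")) {
        dir <- withr::local_tempdir()
        paths <- writeSpatialDataset(ds, dir, format = fmt)
        back <- readSpatialDataset(paths$expression, paths$coordinates,
                                   paths$annotation, format = fmt)
        expect_identical(dim(exprMatrix(back)), dim(exprMatrix(ds)))
        expect_equal(exprMatrix(back), exprMatrix(ds),
                     ignore_attr = TRUE)
        expect_equal(spatialCoords(back), spatialCoords(ds),
                     ignore_attr = TRUE)
        expect_identical(cellTypes(back), cellTypes(ds))
    }

    # shuffled coordinate rows are realigned by shared identifiers
    dir <- withr::local_tempdir()
    paths <- writeSpatialDataset(ds, dir, format = "dense_csv")
    co <- read.csv(paths$coordinates)
    perm <- withr::with_seed(1, sample.int(nrow(co)))
    write.csv(co[perm, ], paths$coordinates, row.names = FALSE)
    back <- readSpatialDataset(paths$expression, paths$coordinates,
                               paths$annotation, format = "dense_csv")
    expect_equal(spatialCoords(back), spatialCoords(ds),
                 ignore_attr = TRUE)
})

test_that("MTX triplet reading matches dense reading, explicit zeros included", {
    dir <- withr::local_tempdir()
    expr <- matrix(c(3, 0, 2, 0, 0, 5), nrow = 3,
                   dimnames = list(paste0("c", 1:3), c("gA", "gB")))
    # coordinate MTX with one explicit zero entry
    mtx <- file.path(dir, "expr.mtx")
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 "3 2 4", "1 1 3", "3 1 2", "3 2 5", "2 1 0"), mtx)
    writeLines(rownames(expr), file.path(dir, "expr.rows.txt"))
    writeLines(colnames(expr), file.path(dir, "expr.cols.txt"))
    coord <- file.path(dir, "coordinates.csv")
    write.csv(data.frame(cell_id = rownames(expr), x = 1:3, y = 0),
              coord, row.names = FALSE)
    csv <- file.path(dir, "expr.csv")
    write.csv(data.frame(cell_id = rownames(expr), expr), csv,
              row.names = FALSE)

    fromMtx <- readSpatialDataset(mtx, coord, format = "mtx_triplet")
    fromCsv <- readSpatialDataset(csv, coord, format = "dense_csv")
    expect_equal(exprMatrix(fromMtx), exprMatrix(fromCsv),
                 ignore_attr = TRUE)
    expect_identical(unname(exprMatrix(fromMtx)[2, 1]), 0)
})

test_that("packaged miniature dataset loads identically from all formats", {
    ext <- function(f) system.file("extdata", f, package = "spanet")
    csv <- readSpatialDataset(ext("synthetic_mini_expression.csv"),
                              ext("synthetic_mini_coordinates.csv"),
                              ext("synthetic_mini_annotation.csv"),
                              format = "dense_csv")
    mtx <- readSpatialDataset(ext("synthetic_mini_expression.mtx"),
                              ext("synthetic_mini_coordinates.csv"),
                              ext("synthetic_mini_annotation.csv"),
                              format = "mtx_triplet")
    expect_identical(nCells(csv), 12L)
    expect_identical(nGenes(csv), 8L)
    expect_equal(exprMatrix(csv), exprMatrix(mtx), ignore_attr = TRUE)
    expect_identical(cellTypes(csv), cellTypes(mtx))
})

test_that("loader rejects misaligned and invalid inputs with informative errors", {
    dir <- withr::local_tempdir()
    ds <- tinyTissue()$ds
    paths <- writeSpatialDataset(ds, dir, format = "dense_csv")
    # coordinate file with too few rows names the offending file
    co <- read.csv(paths$coordinates)
    write.csv(co[-1, ], paths$coordinates, row.names = FALSE)
    expect_error(
        readSpatialDataset(paths$expression, paths$coordinates,
                           format = "dense_csv"),
        "coordinates.csv")
    # negative expression is rejected with the entry identified
    dir2 <- withr::local_tempdir()
    paths2 <- writeSpatialDataset(ds, dir2, format = "dense_csv")
    tab <- read.csv(paths2$expression, check.names = FALSE)
    tab[2, 3] <- -1
    write.csv(tab, paths2$expression, row.names = FALSE)
    expect_error(
        readSpatialDataset(paths2$expression, paths2$coordinates,
                           format = "dense_csv"),
        "negative expression")
    expect_error(
        readSpatialDataset(file.path(dir2, "nope.csv"),
                           paths2$coordinates, format = "dense_csv"),
        "not found")
})

test_that("cropField uses closed intervals, keeps genes, rejects empty crops", {
    expr <- matrix(1, 4, 2, dimnames = list(NULL, c("g1", "g2")))
    ds <- SpatialCellExperiment(expr, cbind(x = c(0, 1, 2, 3), y = 0))
    # full range: identity
    all <- cropField(ds, c(0, 3), c(-1, 1))
    expect_identical(nCells(all), 4L)
    # x in [1,2]: two cells, boundary points retained
    sub <- cropField(ds, c(1, 2), c(-1, 1))
    expect_identical(nCells(sub), 2L)
    expect_identical(nGenes(sub), 2L)
    # a point exactly at x = xmax stays in
    edge <- cropField(ds, c(3, 3), c(-1, 1))
    expect_identical(nCells(edge), 1L)
    expect_error(cropField(ds, c(10, 11), c(-1, 1)), "empty")
})

test_that("simulateTissue is seed-reproducible with valid planted structure", {
    a <- simulateTissue(nCells = 80, nTypes = 3, nGenes = 20,
                        nInformative = 8, seed = 5)
    b <- simulateTissue(nCells = 80, nTypes = 3, nGenes = 20,
                        nInformative = 8, seed = 5)
    expect_identical(exprMatrix(a$dataset), exprMatrix(b$dataset))
    expect_identical(trueEdges(a$truth), trueEdges(b$truth))
    e <- trueEdges(a$truth)
    expect_true(all(e[, 1] < e[, 2]))
    expect_true(all(e >= 1 & e <= 80))
    inf <- informativeGenes(a$truth)
    expect_true(all(inf >= 1 & inf <= 20))
    expect_error(simulateTissue(nCells = 3, seed = 1), "nCells")

    # distal edges planted under the affinity rule connect same-type cells
    d <- simulateTissue(nCells = 150, nTypes = 3, nGenes = 20,
                        nInformative = 8, seed = 9,
                        edgeRule = "proximity_plus_type_affinity",
                        distalFraction = 0.1)
    g <- buildAdjacency(spatialCoords(d$dataset),
                        distanceThreshold = Inf)
    extra <- setdiff(edgeKey(trueEdges(d$truth)), edgeKey(edges(g)))
    expect_gt(length(extra), 0)
    ct <- cellTypes(d$dataset)
    for (k in extra) {
        ij <- as.integer(strsplit(k, " ")[[1]])
        expect_identical(ct[ij[1]], ct[ij[2]])
    }
})

test_that("dropout zeroes the stated fraction of non-zero entries", {
    base <- simulateTissue(nCells = 100, nTypes = 3, nGenes = 40,
                           nInformative = 15, dropoutRate = 0, seed = 3)
    dropped <- simulateTissue(nCells = 100, nTypes = 3, nGenes = 40,
                              nInformative = 15, dropoutRate = 0.4,
                              seed = 3)
    x0 <- exprMatrix(base$dataset)
    x1 <- exprMatrix(dropped$dataset)
    nz <- x0 != 0
    frac <- mean(x1[nz] == 0)
    tol <- 3 * sqrt(0.4 * 0.6 / sum(nz))
    expect_lt(abs(frac - 0.4), tol)
})

test_that("without informative genes expression carries no link signal", {
    # cosine-similarity classifier on expression alone should be at
    # chance when every gene is noise (mean over 30 simulations)
    aurocs <- vapply(seq_len(30), function(s) {
        sim <- simulateTissue(nCells = 60, nTypes = 3, nGenes = 20,
                              nInformative = 0, seed = 100 + s)
        ds <- sim$dataset
        e <- trueEdges(sim$truth)
        n <- nCells(ds)
        X <- scale(log1p(exprMatrix(ds)))
        X[is.na(X)] <- 0
        neg <- withr::with_seed(200 + s, {
            repeat {
                cand <- cbind(sample.int(n, nrow(e), TRUE),
                              sample.int(n, nrow(e), TRUE))
                cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
                if (nrow(cand) >= nrow(e) / 2) break
            }
            cand
        })
        sim1 <- rowSums(X[e[, 1], ] * X[e[, 2], ])
        sim0 <- rowSums(X[neg[, 1], ] * X[neg[, 2], ])
        computeAUROC(sim1, sim0)
    }, numeric(1))
    expect_lt(abs(mean(aurocs) - 0.5), 0.05)
})
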