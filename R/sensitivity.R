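#' @include AllClasses.R vgae-train.R
NULL

#' Shuffle one gene's expression across cells
#'
#' Permutes the chosen column uniformly at random, destroying any
#' association between that gene and cell identity while preserving
#' the column's value multiset. All other columns are untouched.
#'
#' @param X expression matrix (cells x genes)
#' @param geneIndex column to shuffle
#' @param seed integer seed
#' @return the matrix with one column permuted
#' @export
shuffleGene <- function(X, geneIndex, seed = 1L) {
    stopifnot(geneIndex >= 1L, geneIndex <= ncol(X))
    withr::with_seed(as.integer(seed), {
        X[, geneIndex] <- X[sample.int(nrow(X)), geneIndex]
        X
    })
}

#' Per-gene sensitivity scores (permutation importance)
#'
#' Quantifies each gene's contribution to the reconstructed interaction
#' landscape: the gene's expression is shuffled across cells, the
#' (frozen) model re-scores the evaluation edges, and the drop in
#' AUPRC relative to the unperturbed data is recorded. Averaged over
#' `repeats` independent shuffles this is the gene's sensitivity
#' score; genes are ranked by it.
#'
#' By default the trained model is frozen and only the forward pass is
#' repeated (permutation-importance semantics, tractable for
#' genome-scale panels). `retrain = TRUE` refits the full model per
#' shuffle instead; use only for small panels.
#'
#' @param ds the [SpatialCellExperiment-class] the model was trained on
#' @param split the [EdgeSplit-class] used at training (its test sets
#'   are the evaluation sets)
#' @param model the trained [LinkModel-class]
#' @param repeats shuffles per gene (default 30)
#' @param seed integer seed
#' @param retrain refit the model for every shuffle instead of frozen
#'   re-scoring
#' @return data.frame with one row per gene: `gene`, `gene_index`,
#'   `mean_delta_auprc`, `sd_delta_auprc`, `n_repeats`, `rank` (1 =
#'   most sensitive)
#' @export
sensitivityScores <- function(ds, split, model, repeats = 30L,
                              seed = 1L, retrain = FALSE) {
    stopifnot(repeats >= 1L, methods::is(model, "LinkModel"))
    Xraw <- exprMatrix(ds)
    nG <- ncol(Xraw)
    trainGraph <- cellGraph(split@trainPos, nCells(ds))
    Atilde <- normalizeAdjacency(trainGraph)
    ep <- split@testPos; en <- split@testNeg
    if (!nrow(ep) || !nrow(en))
        stop("split must carry non-empty test sets for evaluation")

    prep <- prepareFeatures(Xraw, model@config$normalizeFeatures,
                            model@featureInfo)
    AX0 <- as.matrix(Atilde %*% prep$X)
    H0 <- encoderForward(AX0, Atilde, model@params)$mu
    baseAUPRC <- computeAUPRC(scoreEdges(H0, ep), scoreEdges(H0, en))

    deltas <- matrix(NA_real_, nG, repeats)
    for (g in seq_len(nG)) {
        for (r in seq_len(repeats)) {
            seedGR <- deriveSeed(seed, (g - 1L) * repeats + r)
            if (retrain) {
                Xs <- shuffleGene(Xraw, g, seedGR)
                dsS <- SpatialCellExperiment(
                    Xs, spatialCoords(ds), cellTypes(ds),
                    geneNames(ds), cellIds(ds))
                fit <- trainLinkModel(dsS, split, model@config)
                Hs <- latentMeans(fit)
            } else {
                xg <- withr::with_seed(seedGR,
                    Xraw[sample.int(nrow(Xraw)), g])
                xgp <- if (model@config$normalizeFeatures)
                    (log1p(xg) - prep$info$mean[g]) / prep$info$sd[g]
                else xg
                AX <- AX0
                AX[, g] <- as.numeric(Atilde %*% xgp)
                Hs <- encoderForward(AX, Atilde, model@params)$mu
            }
            deltas[g, r] <- baseAUPRC -
                computeAUPRC(scoreEdges(Hs, ep), scoreEdges(Hs, en))
        }
    }
    meanD <- rowMeans(deltas)
    out <- data.frame(
        gene = geneNames(ds), gene_index = seq_len(nG),
        mean_delta_auprc = meanD,
        sd_delta_auprc = apply(deltas, 1L, stats::sd),
        n_repeats = as.integer(repeats))
    out$rank <- as.integer(rank(-out$mean_delta_auprc,
                                ties.method = "first"))
    out
}

#' Benchmark simple classifiers on gene panels
#'
#' Tests how well a panel of genes separates interacting from
#' non-interacting cell pairs with off-the-shelf classifiers (SVC,
#' k-nearest neighbors, gradient-boosted trees), the protocol used to
#' compare top-ranked sensitivity genes against annotated
#' ligand/receptor panels. Positives are the contact-graph edges;
#' negatives are an equal number of randomly selected non-adjacent
#' pairs. The feature vector of a pair is the concatenation of the two
#' cells' expression over the panel; both orderings are included to
#' respect the undirected nature of the edges. Each repeat redraws the
#' 4:1 train/test assignment; per model, the two panels' AUROC
#' distributions are compared with a Student's t test.
#'
#' @param ds a [SpatialCellExperiment-class]
#' @param graph the contact [CellGraph-class]
#' @param geneSetA,geneSetB integer vectors of gene indices (equal
#'   length for a fair comparison)
#' @param models subset of `c("svc", "knn", "gbdt")`
#' @param repeats number of re-splits (default 30)
#' @param seed integer seed
#' @return data.frame `model`, `gene_set` (`"A"`/`"B"`), `repeat_`,
#'   `auroc`; attribute `"t_tests"` holds the per-model comparison,
#'   attribute `"skipped"` any repeats dropped for degenerate training
#'   sets
#' @export
baselineClassifierBenchmark <- function(ds, graph, geneSetA, geneSetB,
                                        models = c("svc", "knn", "gbdt"),
                                        repeats = 30L, seed = 1L) {
    models <- match.arg(models, several.ok = TRUE)
    stopifnot(length(geneSetA) >= 1L, length(geneSetB) >= 1L)
    X <- exprMatrix(ds)
    n <- nCells(ds)
    pos <- edges(graph)
    m <- nrow(pos)
    neg <- withr::with_seed(as.integer(seed), pairDecode(
        samplePairCodes(n, m, edgeCodes(pos, n)), n))
    pairsAll <- rbind(pos, neg)
    y <- c(rep(1L, m), rep(0L, m))

    pairFeatures <- function(geneSet, idx) {
        e <- pairsAll[idx, , drop = FALSE]
        rbind(cbind(X[e[, 1L], geneSet, drop = FALSE],
                    X[e[, 2L], geneSet, drop = FALSE]),
              cbind(X[e[, 2L], geneSet, drop = FALSE],
                    X[e[, 1L], geneSet, drop = FALSE]))
    }

    fitScore <- function(model, xtr, ytr, xte) {
        if (model == "svc") {
            fit <- e1071::svm(xtr, factor(ytr, levels = c(0L, 1L)),
                              kernel = "radial", scale = TRUE,
                              probability = TRUE)
            attr(stats::predict(fit, xte, probability = TRUE),
                 "probabilities")[, "1"]
        } else if (model == "knn") {
            pr <- class::knn(xtr, xte,
                             factor(ytr, levels = c(0L, 1L)),
                             k = 5L, prob = TRUE)
            votes <- attr(pr, "prob")
            ifelse(pr == "1", votes, 1 - votes)
        } else {
            fit <- xgboost::xgb.train(
                params = list(objective = "binary:logistic",
                              max_depth = 3L, eta = 0.3, nthread = 1L),
                data = xgboost::xgb.DMatrix(xtr, label = ytr),
                nrounds = 50L, verbose = 0)
            stats::predict(fit, xgboost::xgb.DMatrix(xte))
        }
    }

    rows <- list(); skipped <- character(0)
    for (r in seq_len(repeats)) {
        seedR <- deriveSeed(seed, r)
        trIdx <- withr::with_seed(seedR,
            sample.int(2L * m, round(0.8 * 2L * m)))
        teIdx <- setdiff(seq_len(2L * m), trIdx)
        if (length(unique(y[trIdx])) < 2L ||
            length(unique(y[teIdx])) < 2L) {
            skipped <- c(skipped, sprintf("repeat %d: single-class set", r))
            next
        }
        for (setName in c("A", "B")) {
            gs <- if (setName == "A") geneSetA else geneSetB
            xtr <- pairFeatures(gs, trIdx)
            ytr <- rep(y[trIdx], 2L)
            xte <- pairFeatures(gs, teIdx)
            for (mod in models) {
                sc <- withr::with_seed(deriveSeed(seedR, 13L),
                                       fitScore(mod, xtr, ytr, xte))
                # average the two orderings of each test pair
                scPair <- (sc[seq_along(teIdx)] +
                           sc[seq_along(teIdx) + length(teIdx)]) / 2
                rows[[length(rows) + 1L]] <- data.frame(
                    model = mod, gene_set = setName, repeat_ = r,
                    auroc = computeAUROC(scPair[y[teIdx] == 1L],
                                         scPair[y[teIdx] == 0L]))
            }
        }
    }
    out <- do.call(rbind, rows)
    tt <- do.call(rbind, lapply(unique(out$model), function(mod) {
        a <- out$auroc[out$model == mod & out$gene_set == "A"]
        b <- out$auroc[out$model == mod & out$gene_set == "B"]
        ht <- stats::t.test(a, b, var.equal = TRUE)
        data.frame(model = mod, mean_auroc_a = mean(a),
                   mean_auroc_b = mean(b),
                   t = unname(ht$statistic), p_value = ht$p.value)
    }))
    attr(out, "t_tests") <- tt
    if (length(skipped)) attr(out, "skipped") <- skipped
    out
}
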