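#' @include AllClasses.R vgae-math.R
NULL

#' Model configuration
#'
#' Collects the architecture and optimization settings of the
#' adversarially regularized variational graph autoencoder. The
#' defaults follow the reference setup: a two-layer graph convolutional
#' encoder (250 hidden, 125 latent units), a 125-150 fully connected
#' discriminator with ReLU activations, and Adam with learning rate
#' 4e-4.
#'
#' @param hidden width of the shared first GCN layer
#' @param latent latent dimensionality (posterior mean / log-sigma
#'   heads)
#' @param discHidden integer vector of the two discriminator hidden
#'   widths
#' @param learningRate Adam step size
#' @param epochs training epochs (one discriminator and one
#'   encoder/decoder step per epoch)
#' @param dropoutRate dropout on the hidden GCN layer during training
#' @param adversarialWeight weight of the generator's adversarial term
#'   relative to the negative ELBO
#' @param seed integer; initialization and all training noise derive
#'   from it
#' @param normalizeFeatures if `TRUE`, expression is log1p-transformed
#'   and z-scored per gene before encoding; if `FALSE` (default) values
#'   are fed as loaded
#' @param earlyStopping monitor a validation split carved from the
#'   training edges (5%) and stop when its AUROC stops improving
#' @param patience epochs without improvement tolerated when
#'   `earlyStopping` is on
#' @param logEvery evaluate held-out AUROC every this many epochs
#' @return a validated config list
#' @export
linkModelConfig <- function(hidden = 250L, latent = 125L,
                            discHidden = c(125L, 150L),
                            learningRate = 4e-4, epochs = 300L,
                            dropoutRate = 0.2, adversarialWeight = 1,
                            seed = 1L, normalizeFeatures = FALSE,
                            earlyStopping = FALSE, patience = 50L,
                            logEvery = 10L) {
    cfg <- list(hidden = as.integer(hidden), latent = as.integer(latent),
                discHidden = as.integer(discHidden),
                learningRate = learningRate, epochs = as.integer(epochs),
                dropoutRate = dropoutRate,
                adversarialWeight = adversarialWeight,
                seed = as.integer(seed),
                normalizeFeatures = isTRUE(normalizeFeatures),
                earlyStopping = isTRUE(earlyStopping),
                patience = as.integer(patience),
                logEvery = as.integer(logEvery))
    stopifnot(cfg$hidden > 0L, cfg$latent > 0L,
              length(cfg$discHidden) == 2L, all(cfg$discHidden > 0L),
              cfg$learningRate > 0, cfg$epochs >= 0L,
              cfg$dropoutRate >= 0, cfg$dropoutRate < 1,
              cfg$adversarialWeight >= 0)
    cfg
}

#' Symmetrically normalized adjacency
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)`, where `D` is the degree matrix
#' of `A + I`; the self-loop guarantees positive degrees, so isolated
#' cells remain valid (their row reduces to the 1.0 self-entry).
#'
#' @param graph a [CellGraph-class], or a symmetric 0/1 adjacency
#'   matrix
#' @return a sparse symmetric matrix
#' @examples
#' g <- cellGraph(cbind(1, 2), nCells = 2)
#' as.matrix(normalizeAdjacency(g))   # all entries 0.5
#' @export
normalizeAdjacency <- function(graph) {
    A <- if (methods::is(graph, "CellGraph")) adjacencyMatrix(graph)
         else Matrix::Matrix(graph, sparse = TRUE)
    AI <- A + Matrix::Diagonal(nrow(A))
    dinv <- 1 / sqrt(Matrix::rowSums(AI))
    Matrix::Diagonal(x = dinv) %*% AI %*% Matrix::Diagonal(x = dinv)
}

#' Encode cells into the variational latent space
#'
#' One forward pass of the graph-convolutional encoder:
#' `hidden = ReLU(Atilde X W0)` (with dropout in train mode), then
#' `mu = Atilde hidden W1mu` and `log sigma = Atilde hidden W1sig`
#' (both linear). In train mode the sample is drawn by
#' reparameterization, `H = mu + exp(log sigma) * eps`; in eval mode
#' `H = mu`.
#'
#' @param X feature matrix, cells x genes (already preprocessed)
#' @param Atilde normalized adjacency from [normalizeAdjacency()]
#' @param params encoder weight list (`W0`, `W1mu`, `W1sig`)
#' @param dropoutRate dropout probability on the hidden layer (train
#'   mode only)
#' @param mode `"eval"` (deterministic) or `"train"`
#' @return a [LatentEmbedding-class]
#' @export
encodeCells <- function(X, Atilde, params, dropoutRate = 0,
                        mode = c("eval", "train")) {
    mode <- match.arg(mode)
    AX <- as.matrix(Atilde %*% X)
    if (mode == "train") {
        mask <- matrix(as.numeric(
            runif(nrow(X) * ncol(params$W0)) >= dropoutRate),
            nrow(X), ncol(params$W0))
        eps <- matrix(rnorm(nrow(X) * ncol(params$W1mu)),
                      nrow(X), ncol(params$W1mu))
        fw <- encoderForward(AX, Atilde, params, dropMask = mask,
                             keep = 1 - dropoutRate, eps = eps)
    } else {
        fw <- encoderForward(AX, Atilde, params)
    }
    if (any(!is.finite(fw$H)))
        stop("non-finite activations in the encoder forward pass")
    methods::new("LatentEmbedding", mu = fw$mu, logSigma = fw$ls,
                 sample = fw$H)
}

#' Inner-product decoder
#'
#' Decodes a latent matrix into interaction probabilities,
#' `sigmoid(H H^T)`. The diagonal is reported but never enters losses
#' or metrics.
#'
#' @param H latent matrix (cells x latent), or a
#'   [LatentEmbedding-class] (its sample is used)
#' @return symmetric numeric matrix of probabilities in (0, 1)
#' @export
decodeLatent <- function(H) {
    if (methods::is(H, "LatentEmbedding")) H <- H@sample
    sigmoid(H %*% t(H))
}

#' Negative evidence lower bound
#'
#' The training objective of the variational part: class-rebalanced
#' binary cross-entropy between decoded probabilities and the observed
#' adjacency (off-diagonal pairs only; positives up-weighted by the
#' non-edge/edge ratio and the term rescaled as in standard sparse-graph
#' VGAE practice), plus the closed-form KL divergence of the diagonal
#' Gaussian posterior from the standard normal prior, averaged over
#' cells.
#'
#' @param probs symmetric probability matrix from [decodeLatent()]
#' @param A 0/1 adjacency matrix (diagonal ignored)
#' @param mu,logSigma posterior parameters, cells x latent
#' @return list with `loss` (negative ELBO), `recon` and `kl`
#' @export
elboLoss <- function(probs, A, mu, logSigma) {
    n <- nrow(A)
    A <- as.matrix(A)
    w <- reconWeights(n, sum(A) / 2)
    offdiag <- 1 - diag(n)
    eps <- 1e-12
    bce <- (w$posWeight * A * (-log(pmax(probs, eps))) +
            (1 - A) * (-log(pmax(1 - probs, eps)))) * offdiag
    recon <- w$norm / w$nPairs * 0.5 * sum(bce)
    kl <- 0.5 * sum(mu^2 + exp(2 * logSigma) - 1 - 2 * logSigma) / n^2
    list(loss = recon + kl, recon = recon, kl = kl)
}

#' Discriminator forward pass
#'
#' Scores latent vectors with the adversarial discriminator: a
#' multilayer perceptron with two ReLU hidden layers and a sigmoid
#' output judging whether a sample came from the Gaussian prior (high
#' scores) or from the encoder.
#'
#' @param H matrix of latent vectors (rows = samples)
#' @param params weight list carrying `Wd1`, `bd1`, `Wd2`, `bd2`,
#'   `wd3`, `bd3`
#' @return numeric vector of probabilities, one per row, order
#'   preserved
#' @export
discriminatorForward <- function(H, params) {
    as.numeric(discForward(as.matrix(H), params)$p)
}

# feature preprocessing used at train time, reproducible at rescore
# time via the stored featureInfo
prepareFeatures <- function(X, normalize, info = NULL) {
    if (!normalize) return(list(X = X, info = list(normalize = FALSE)))
    Xl <- log1p(X)
    if (is.null(info)) {
        mu <- colMeans(Xl)
        sdv <- apply(Xl, 2L, stats::sd)
        sdv[sdv == 0] <- 1
        info <- list(normalize = TRUE, mean = mu, sd = sdv)
    }
    Xs <- sweep(sweep(Xl, 2L, info$mean, "-"), 2L, info$sd, "/")
    list(X = Xs, info = info)
}

#' Train the adversarial variational graph autoencoder
#'
#' Whole-graph training with alternating updates per epoch: (1) the
#' discriminator takes one Adam step on binary cross-entropy between
#' prior samples (label 1) and current encoder samples (label 0); (2)
#' the encoder/decoder takes one Adam step on the negative ELBO plus
#' `adversarialWeight` times the generator term (encoder samples scored
#' against label 1). Only the training-split edges enter the
#' reconstruction target and the graph convolution; held-out edges are
#' invisible during training. The run is fully reproducible from
#' `config$seed`.
#'
#' @param ds a [SpatialCellExperiment-class]
#' @param split an [EdgeSplit-class] from [splitEdges()]
#' @param config a [linkModelConfig()] list
#' @return a [LinkModel-class]; its embedding is the deterministic
#'   eval-mode encoding of the training data and its log records
#'   per-epoch losses and periodic held-out AUROC
#' @examples
#' \donttest{
#' sim <- simulateTissue(nCells = 150, nGenes = 30, seed = 7)
#' g <- buildAdjacency(spatialCoords(sim$dataset))
#' sp <- splitEdges(g, seed = 7)
#' cfg <- linkModelConfig(hidden = 32, latent = 16, epochs = 50,
#'                        normalizeFeatures = TRUE, seed = 7)
#' fit <- trainLinkModel(sim$dataset, sp, cfg)
#' fit
#' }
#' @export
trainLinkModel <- function(ds, split, config = linkModelConfig()) {
    stopifnot(methods::is(ds, "SpatialCellExperiment"),
              methods::is(split, "EdgeSplit"))
    if (nrow(split@trainPos) == 0L) stop("no training edges")
    n <- nCells(ds)
    prep <- prepareFeatures(exprMatrix(ds), config$normalizeFeatures)
    X <- prep$X

    trainPos <- split@trainPos
    valPos <- matrix(integer(0), 0L, 2L)
    valNeg <- matrix(integer(0), 0L, 2L)

    withr::with_seed(config$seed, {
        if (config$earlyStopping && nrow(trainPos) >= 20L) {
            nVal <- max(1L, round(0.05 * nrow(trainPos)))
            vi <- sample.int(nrow(trainPos), nVal)
            valPos <- trainPos[vi, , drop = FALSE]
            trainPos <- trainPos[-vi, , drop = FALSE]
            excl <- edgeCodes(rbind(split@trainPos, split@testPos,
                                    split@testNeg), n)
            valNeg <- pairDecode(samplePairCodes(n, nVal, excl), n)
        }

        trainGraph <- cellGraph(trainPos, n)
        Atilde <- normalizeAdjacency(trainGraph)
        AX <- as.matrix(Atilde %*% X)
        A <- as.matrix(adjacencyMatrix(trainGraph))

        params <- initParams(ncol(X), config)
        genNames <- c("W0", "W1mu", "W1sig")
        discNames <- c("Wd1", "bd1", "Wd2", "bd2", "wd3", "bd3")
        adamG <- adamInit(params[genNames])
        adamD <- adamInit(params[discNames])

        trainLog <- vector("list", config$epochs)
        keep <- 1 - config$dropoutRate
        bestVal <- -Inf; sinceBest <- 0L
        evalAUROC <- function(p, e0, e1) {
            H <- encoderForward(AX, Atilde, p)$mu
            if (nrow(e0) && nrow(e1))
                computeAUROC(scoreEdges(H, e0), scoreEdges(H, e1))
            else NA_real_
        }

        for (epoch in seq_len(config$epochs)) {
            mask <- if (config$dropoutRate > 0)
                matrix(as.numeric(runif(n * config$hidden) >=
                                  config$dropoutRate), n, config$hidden)
            else NULL
            eps <- matrix(rnorm(n * config$latent), n, config$latent)

            # discriminator step (encoder samples detached)
            fwd <- encoderForward(AX, Atilde, params, mask, keep, eps)
            zPrior <- matrix(rnorm(n * config$latent), n, config$latent)
            dres <- discriminatorLossGrads(zPrior, fwd$H, params)
            upd <- adamStep(params[discNames], dres$grads, adamD,
                            config$learningRate)
            params[discNames] <- upd$params
            adamD <- upd$state

            # encoder/decoder step against the updated discriminator
            gres <- generatorLossGrads(X, AX, Atilde, A, params, config,
                                       mask, eps)
            if (!is.finite(gres$loss))
                stop(sprintf(
                    "training diverged at epoch %d (non-finite loss)",
                    epoch))
            upd <- adamStep(params[genNames], gres$grads, adamG,
                            config$learningRate)
            params[genNames] <- upd$params
            adamG <- upd$state

            doEval <- epoch %% config$logEvery == 0L ||
                epoch == config$epochs
            testA <- if (doEval)
                evalAUROC(params, split@testPos, split@testNeg)
            else NA_real_
            trainLog[[epoch]] <- data.frame(
                epoch = epoch, loss = gres$loss, recon = gres$recon,
                kl = gres$kl, adversarial = gres$adv,
                disc_loss = dres$loss, test_auroc = testA)

            if (config$earlyStopping && doEval && nrow(valPos)) {
                valA <- evalAUROC(params, valPos, valNeg)
                if (valA > bestVal + 1e-6) {
                    bestVal <- valA; sinceBest <- 0L
                } else {
                    sinceBest <- sinceBest + config$logEvery
                    if (sinceBest >= config$patience) {
                        trainLog <- trainLog[seq_len(epoch)]
                        break
                    }
                }
            }
        }

        fwEval <- encoderForward(AX, Atilde, params)
        emb <- methods::new("LatentEmbedding", mu = fwEval$mu,
                            logSigma = fwEval$ls, sample = fwEval$mu)
        methods::new(
            "LinkModel", config = config, params = params,
            embedding = emb,
            log = if (config$epochs > 0L)
                do.call(rbind,
                        trainLog[!vapply(trainLog, is.null, TRUE)])
            else data.frame(),
            featureInfo = prep$info)
    })
}

# eval-mode embedding of (possibly modified) expression under a frozen
# model; Atilde/AX may be precomputed by hot loops
frozenEmbedding <- function(model, X, Atilde, AX = NULL) {
    Xp <- prepareFeatures(X, model@config$normalizeFeatures,
                          model@featureInfo)$X
    if (is.null(AX)) AX <- as.matrix(Atilde %*% Xp)
    encoderForward(AX, Atilde, model@params)$mu
}
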