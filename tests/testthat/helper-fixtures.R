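# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (!exists(name, envir = .fixtures))
        assign(name, build(), envir = .fixtures)
    get(name, envir = .fixtures)
}

# small tissue for fast structural tests
tinyTissue <- function() {
    fixture("tiny", function() {
        sim <- simulateTissue(nCells = 120, nTypes = 3, nGenes = 30,
                              nInformative = 12, seed = 42)
        g <- buildAdjacency(spatialCoords(sim$dataset))
        list(sim = sim, ds = sim$dataset, graph = g)
    })
}

# a trained model on a mid-size tissue, reused wherever a fitted model
# is needed (problem sizes chosen to keep one training under ~10 s)
smallTrained <- function() {
    fixture("trained", function() {
        sim <- simulateTissue(nCells = 200, nTypes = 4, nGenes = 40,
                              nInformative = 16, seed = 7)
        g <- buildAdjacency(spatialCoords(sim$dataset))
        sp <- splitEdges(g, 0.1, 50, seed = 7)
        cfg <- linkModelConfig(hidden = 64, latent = 32, epochs = 120,
                               normalizeFeatures = TRUE, seed = 7)
        fit <- trainLinkModel(sim$dataset, sp, cfg)
        list(sim = sim, ds = sim$dataset, graph = g, split = sp,
             config = cfg, fit = fit)
    })
}

# brute-force AUROC over all positive/negative pairs (independent
# oracle for the rank/trapezoid implementations)
bruteAUROC <- function(pos, neg) {
    wins <- 0
    for (p in pos) for (q in neg)
        wins <- wins + (p > q) + 0.5 * (p == q)
    wins / (length(pos) * length(neg))
}

# brute-force AUPRC by explicit threshold sweep (step interpolation)
bruteAUPRC <- function(pos, neg) {
    thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
    prevR <- 0; area <- 0
    for (t in thr) {
        tp <- sum(pos >= t); fp <- sum(neg >= t)
        prec <- tp / (tp + fp); rec <- tp / length(pos)
        area <- area + (rec - prevR) * prec
        prevR <- rec
    }
    area
}

# edge matrices as canonical key sets, for set comparisons
edgeKey <- function(e) {
    if (!nrow(e)) return(character(0))
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}
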