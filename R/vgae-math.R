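# Internal numerics of the adversarially regularized variational graph
# autoencoder: forward passes, analytic gradients, Adam updates.
# Everything here is deterministic given its inputs; stochasticity
# (reparameterization noise, dropout masks, prior samples) is drawn by
# the training loop and passed in, which is also what makes the
# finite-difference gradient checks possible.

glorot <- function(nin, nout) {
    r <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -r, r), nin, nout)
}

initParams <- function(nGenes, config) {
    h <- config$hidden; d <- config$latent
    dh <- config$discHidden
    # biases get small uniform noise rather than zeros: an all-zero
    # bias leaves whole ReLU pre-activation rows exactly at the kink
    list(W0 = glorot(nGenes, h),
         W1mu = glorot(h, d),
         W1sig = glorot(h, d),
         Wd1 = glorot(d, dh[1L]), bd1 = runif(dh[1L], -0.1, 0.1),
         Wd2 = glorot(dh[1L], dh[2L]), bd2 = runif(dh[2L], -0.1, 0.1),
         wd3 = glorot(dh[2L], 1L), bd3 = runif(1L, -0.1, 0.1))
}

LOGSIG_CLAMP <- 10

# encoder forward pass. AX = Atilde %*% X precomputed by the caller.
# dropMask (0/1 matrix over the hidden layer) and eps are optional; in
# eval mode the sample equals the posterior mean.
encoderForward <- function(AX, Atilde, params, dropMask = NULL,
                           keep = 1, eps = NULL) {
    M <- AX %*% params$W0
    Hid <- pmax(M, 0)
    Hd <- if (is.null(dropMask)) Hid else Hid * dropMask / keep
    AH <- as.matrix(Atilde %*% Hd)
    mu <- AH %*% params$W1mu
    lsRaw <- AH %*% params$W1sig
    ls <- pmin(pmax(lsRaw, -LOGSIG_CLAMP), LOGSIG_CLAMP)
    H <- if (is.null(eps)) mu else mu + exp(ls) * eps
    list(M = M, Hid = Hid, Hd = Hd, AH = AH, mu = mu,
         lsRaw = lsRaw, ls = ls, H = H)
}

# discriminator forward pass; returns intermediates for backprop
discForward <- function(H, params) {
    a1 <- sweep(H %*% params$Wd1, 2L, params$bd1, "+")
    r1 <- pmax(a1, 0)
    a2 <- sweep(r1 %*% params$Wd2, 2L, params$bd2, "+")
    r2 <- pmax(a2, 0)
    a3 <- r2 %*% params$wd3 + params$bd3
    list(a1 = a1, r1 = r1, a2 = a2, r2 = r2, a3 = a3,
         p = sigmoid(a3))
}

# backprop through the discriminator given dL/da3; returns parameter
# gradients and, optionally, the gradient w.r.t. the input batch
discBackward <- function(fwd, H, params, dA3, wantInputGrad = FALSE) {
    dr2 <- tcrossprod(dA3, params$wd3)
    da2 <- dr2 * (fwd$a2 > 0)
    dr1 <- tcrossprod(da2, params$Wd2)
    da1 <- dr1 * (fwd$a1 > 0)
    out <- list(wd3 = crossprod(fwd$r2, dA3), bd3 = sum(dA3),
                Wd2 = crossprod(fwd$r1, da2), bd2 = colSums(da2),
                Wd1 = crossprod(H, da1), bd1 = colSums(da1))
    if (wantInputGrad) out$dH <- tcrossprod(da1, params$Wd1)
    out
}

# class-rebalanced reconstruction loss over off-diagonal pairs:
# positives weighted by (#pairs - #edges)/#edges and the whole term
# scaled by #pairs / (2 (#pairs - #edges)) -- the usual VGAE
# norm/pos_weight scheme, required because contact graphs are sparse
reconWeights <- function(n, nEdgesTrain) {
    nPairs <- n * (n - 1) / 2
    list(posWeight = (nPairs - nEdgesTrain) / nEdgesTrain,
         norm = nPairs / (2 * (nPairs - nEdgesTrain)),
         nPairs = nPairs)
}

# loss + gradients of the generator objective (negative ELBO +
# adversarial term) for fixed noise. A is the dense 0/1 training
# adjacency (diagonal ignored). Returns loss components and gradients
# for the encoder weights.
generatorLossGrads <- function(X, AX, Atilde, A, params, config,
                               dropMask = NULL, eps = NULL) {
    n <- nrow(A)
    fw <- encoderForward(AX, Atilde, params, dropMask,
                         keep = 1 - config$dropoutRate, eps = eps)
    H <- fw$H
    S <- tcrossprod(H)
    P <- sigmoid(S)
    w <- reconWeights(n, sum(A) / 2)

    offdiag <- 1 - diag(n)
    bceMat <- (w$posWeight * A * softplus(-S) +
               (1 - A) * softplus(S)) * offdiag
    recon <- w$norm / w$nPairs * 0.5 * sum(bceMat)

    kl <- 0.5 * sum(fw$mu^2 + exp(2 * fw$ls) - 1 - 2 * fw$ls) / n^2

    # adversarial generator term: encoder samples scored against the
    # "came from the prior" label
    dfw <- discForward(H, params)
    adv <- mean(softplus(-dfw$a3))

    loss <- recon + kl + config$adversarialWeight * adv

    # --- backward ---
    G <- (w$norm / w$nPairs * 0.5) *
        (w$posWeight * A * (P - 1) + (1 - A) * P) * offdiag
    dH <- 2 * (G %*% H)                      # G symmetric, diag zero
    dA3 <- (dfw$p - 1) / n
    db <- discBackward(dfw, H, params, dA3, wantInputGrad = TRUE)
    dH <- dH + config$adversarialWeight * db$dH

    dmu <- dH + fw$mu / n^2
    sig <- exp(fw$ls)
    clampOK <- abs(fw$lsRaw) < LOGSIG_CLAMP
    dls <- (sig^2 - 1) / n^2
    if (!is.null(eps)) dls <- dls + dH * eps * sig
    dls <- dls * clampOK

    dW1mu <- crossprod(fw$AH, dmu)
    dW1sig <- crossprod(fw$AH, dls)
    dAH <- tcrossprod(dmu, params$W1mu) + tcrossprod(dls, params$W1sig)
    dHd <- as.matrix(Atilde %*% dAH)
    dHid <- if (is.null(dropMask)) dHd else
        dHd * dropMask / (1 - config$dropoutRate)
    dM <- dHid * (fw$M > 0)
    dW0 <- crossprod(AX, dM)

    list(loss = loss, recon = recon, kl = kl, adv = adv,
         grads = list(W0 = dW0, W1mu = dW1mu, W1sig = dW1sig),
         forward = fw)
}

# discriminator objective: binary cross-entropy, prior samples labeled
# 1 and (detached) encoder samples labeled 0
discriminatorLossGrads <- function(zPrior, H, params) {
    n <- nrow(H)
    fr <- discForward(zPrior, params)
    ff <- discForward(H, params)
    loss <- 0.5 * (mean(softplus(-fr$a3)) + mean(softplus(ff$a3)))
    gr <- discBackward(fr, zPrior, params, 0.5 * (fr$p - 1) / n)
    gf <- discBackward(ff, H, params, 0.5 * ff$p / n)
    grads <- Map(`+`, gr, gf)
    list(loss = loss, grads = grads)
}

adamInit <- function(params) {
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9,
                     beta2 = 0.999, epsilon = 1e-8) {
    state$t <- state$t + 1L
    for (nm in names(grads)) {
        g <- grads[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        mhat <- state$m[[nm]] / (1 - beta1^state$t)
        vhat <- state$v[[nm]] / (1 - beta2^state$t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + epsilon)
    }
    list(params = params, state = state)
}
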