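#' @include AllClasses.R
NULL

#' Area under the ROC curve
#'
#' Two algebraically equivalent routes are provided: `"rank"` computes
#' the Mann-Whitney statistic, `P(score_pos > score_neg) + 0.5 P(tie)`
#' over all positive/negative pairs; `"trapezoid"` integrates the ROC
#' curve over descending unique score thresholds with the trapezoidal
#' rule (equal scores collapse onto one ROC vertex, which reproduces
#' the half-credit tie convention). The two agree to machine precision
#' and serve as mutual oracles.
#'
#' @param scoresPos,scoresNeg numeric vectors of scores for the
#'   positive and negative instances (both non-empty)
#' @param method `"rank"` (default) or `"trapezoid"`
#' @return AUROC in `[0, 1]`
#' @examples
#' computeAUROC(c(0.9, 0.4), c(0.6, 0.1))   # 0.75
#' @export
computeAUROC <- function(scoresPos, scoresNeg,
                         method = c("rank", "trapezoid")) {
    method <- match.arg(method)
    if (!length(scoresPos) || !length(scoresNeg))
        stop("both score vectors must be non-empty")
    nP <- length(scoresPos); nN <- length(scoresNeg)
    if (method == "rank") {
        r <- rank(c(scoresPos, scoresNeg))
        (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nN)
    } else {
        s <- c(scoresPos, scoresNeg)
        lab <- c(rep(1L, nP), rep(0L, nN))
        o <- order(s, decreasing = TRUE)
        s <- s[o]; lab <- lab[o]
        grp <- cumsum(!duplicated(s))
        tp <- c(0, cumsum(tapply(lab, grp, sum)))
        fp <- c(0, cumsum(tapply(1L - lab, grp, sum)))
        tpr <- tp / nP; fpr <- fp / nN
        sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    }
}

#' Area under the precision-recall curve
#'
#' Step interpolation over descending unique thresholds: at each
#' threshold the achieved precision is held over the recall increment,
#' `sum (R_k - R_(k-1)) P_k`.
#'
#' @inheritParams computeAUROC
#' @return AUPRC in `(0, 1]`
#' @export
computeAUPRC <- function(scoresPos, scoresNeg) {
    if (!length(scoresPos) || !length(scoresNeg))
        stop("both score vectors must be non-empty")
    nP <- length(scoresPos)
    s <- c(scoresPos, scoresNeg)
    lab <- c(rep(1L, nP), rep(0L, length(scoresNeg)))
    o <- order(s, decreasing = TRUE)
    s <- s[o]; lab <- lab[o]
    grp <- cumsum(!duplicated(s))
    tp <- cumsum(tapply(lab, grp, sum))
    pred <- cumsum(tapply(rep(1L, length(lab)), grp, sum))
    precision <- tp / pred
    recall <- tp / nP
    sum(diff(c(0, recall)) * precision)
}

#' False positive rate at a score threshold
#'
#' Fraction of negatives scoring at or above `threshold` (the >=
#' convention matches network assembly, where edges at the threshold
#' are kept).
#'
#' @param scoresNeg numeric vector of negative-instance scores
#' @param threshold numeric cutoff
#' @return fraction in `[0, 1]`
#' @export
computeFprAtThreshold <- function(scoresNeg, threshold) {
    if (!length(scoresNeg)) stop("empty negative score vector")
    mean(scoresNeg >= threshold)
}
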