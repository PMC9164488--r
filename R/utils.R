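# internal numerics + pair-index helpers shared across modules

sigmoid <- function(x) stats::plogis(x)

# numerically stable log(1 + exp(x))
softplus <- function(x) {
    pmax(x, 0) + log1p(exp(-abs(x)))
}

# Unordered pairs (i < j) over n cells are enumerated column-major:
# code(i, j) = (i - 1) * n - i * (i + 1) / 2 + j. Codes are 1..n(n-1)/2
# and let us sample non-edges without materializing all pairs.
pairCode <- function(i, j, n) {
    (i - 1) * n - i * (i + 1) / 2 + j
}

pairDecode <- function(code, n) {
    # invert pairCode: find i such that cumulative count passes 'code';
    # the closed form can be off by one at block boundaries, so correct
    i <- ceiling(n - 0.5 - sqrt(pmax((n - 0.5)^2 - 2 * code, 0)))
    i <- pmax(pmin(i, n - 1), 1)
    j <- code - (i - 1) * n + i * (i + 1) / 2
    low <- j <= i
    i[low] <- i[low] - 1L
    high <- !low & j > n
    i[high] <- i[high] + 1L
    j <- code - (i - 1) * n + i * (i + 1) / 2
    stopifnot(all(j > i), all(j <= n))
    cbind(i = as.integer(i), j = as.integer(j))
}

# sample 'size' distinct pair codes uniformly from the complement of
# 'excludeCodes' within 1..n(n-1)/2 (rejection sampling; the excluded
# set is always sparse here)
samplePairCodes <- function(n, size, excludeCodes = numeric()) {
    total <- n * (n - 1) / 2
    avail <- total - length(excludeCodes)
    if (size > avail)
        stop(sprintf(
            "requested %d pairs but only %d non-excluded pairs exist",
            size, avail))
    got <- numeric(0)
    excl <- c(excludeCodes, got)
    while (length(got) < size) {
        draw <- ceiling(runif(2L * (size - length(got)) + 10L) * total)
        draw <- draw[!(draw %in% excl)]
        draw <- draw[!duplicated(draw)]
        got <- c(got, draw)
        excl <- c(excludeCodes, got)
    }
    got[seq_len(size)]
}

edgeCodes <- function(e, n) {
    if (!nrow(e)) return(numeric(0))
    pairCode(e[, 1L], e[, 2L], n)
}

# Euclidean lengths of a set of edges
edgeLengths <- function(e, coords) {
    if (!nrow(e)) return(numeric(0))
    sqrt((coords[e[, 1L], 1L] - coords[e[, 2L], 1L])^2 +
         (coords[e[, 1L], 2L] - coords[e[, 2L], 2L])^2)
}

# score edges under a latent embedding: sigmoid(h_i . h_j)
scoreEdges <- function(H, e) {
    if (!nrow(e)) return(numeric(0))
    sigmoid(rowSums(H[e[, 1L], , drop = FALSE] *
                    H[e[, 2L], , drop = FALSE]))
}

# derive a stream of reproducible sub-seeds from one base seed,
# keeping everything inside 32-bit integer range
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}
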