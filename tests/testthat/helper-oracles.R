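# Independent oracles used across the suite.  They deliberately avoid the
# package's closed-form code paths: extrema by enumeration of feasible
# contingency tables, the Pearson floor by constructing the worst-case
# arrangement, AUC by brute-force concordance counting.

# min/max of the Phi coefficient over all integer-feasible co-occurrence
# counts for occupancy counts (a, b) out of n samples
bruteForcePhiExtrema <- function(a, b, n) {
    pA <- a / n; pB <- b / n
    k <- seq(max(0L, a + b - n), min(a, b))
    phi <- (k / n - pA * pB) / sqrt(pA * (1 - pA) * pB * (1 - pB))
    c(min = min(phi), max = max(phi))
}

# worst-case Pearson correlation: disjoint supports, constant positive
# abundance (only defined when a + b <= n)
worstCasePearson <- function(a, b, n) {
    x <- c(rep(1, a), rep(0, n - a))
    y <- c(rep(0, n - b), rep(1, b))
    stats::cor(x, y)
}

# AUC by direct concordance counting (ties count 1/2)
bruteForceAuc <- function(score, label) {
    pos <- score[label]; neg <- score[!label]
    s <- 0
    for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
    s / (length(pos) * length(neg))
}

# average precision by direct enumeration over distinct thresholds
bruteForceAveragePrecision <- function(score, label) {
    ths <- sort(unique(score), decreasing = TRUE)
    nPos <- sum(label)
    ap <- 0; prevTp <- 0
    for (t in ths) {
        sel <- score >= t
        tp <- sum(label[sel])
        ap <- ap + (tp - prevTp) / nPos * (tp / sum(sel))
        prevTp <- tp
    }
    ap
}

# hand-rolled EdgeScores for evaluation tests
makeEdgeScores <- function(scoreMat, masked = NULL) {
    p <- nrow(scoreMat)
    idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
    if (is.null(masked)) masked <- matrix(FALSE, p, p)
    sc <- scoreMat[idx]
    sc[masked[idx]] <- 0
    new("EdgeScores",
        pairs = data.frame(i = idx[, 1L], j = idx[, 2L],
                           otu_i = paste0("OTU", idx[, 1L]),
                           otu_j = paste0("OTU", idx[, 2L]),
                           score = sc, masked = masked[idx]),
        nOtus = as.integer(p), config = list(filterMode = "none"))
}
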