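#' Phi coefficient between two count vectors
#'
#' Binarizes both vectors at zero (presence = count > 0) and computes the
#' Pearson correlation of the two indicators,
#' \eqn{\phi = (P_{11} - P_A P_B) / \sqrt{P_A(1-P_A)P_B(1-P_B)}}.
#' Undefined (NA, with a warning) when either indicator is constant.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return the Phi coefficient in [-1, 1], or NA if undefined.
#' @examples
#' phiCoefficient(c(1, 2, 0, 0), c(3, 1, 0, 0))  # 1
#' @export
phiCoefficient <- function(x, y) {
    stopifnot(length(x) == length(y))
    a <- x > 0; b <- y > 0
    pA <- mean(a); pB <- mean(b)
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
        warning("phi undefined: constant occurrence vector", call. = FALSE)
        return(NA_real_)
    }
    (mean(a & b) - pA * pB) / sqrt(pA * (1 - pA) * pB * (1 - pB))
}

#' Bray-Curtis dissimilarity between two OTU abundance profiles
#'
#' \eqn{BC = 1 - 2\sum_i \min(x_i, y_i) / \sum_i (x_i + y_i)}, computed
#' between the two OTU vectors across samples (the ecological statistic
#' repurposed as an OTU-pair association measure).  Delegates to
#' \code{vegan::vegdist}.
#'
#' @inheritParams phiCoefficient
#' @return dissimilarity in [0, 1]; NA (with a warning) if both vectors
#'   are all zero.
#' @examples
#' brayCurtis(c(1, 1), c(1, 3))  # 1 - 2*2/6
#' @export
brayCurtis <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (sum(x) + sum(y) == 0) {
        warning("Bray-Curtis undefined: both profiles empty", call. = FALSE)
        return(NA_real_)
    }
    as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

.binZeroQuantile <- function(x, nBins) {
    b <- integer(length(x))
    pos <- x > 0
    if (any(pos)) {
        xp <- x[pos]
        qs <- unique(stats::quantile(xp, probs = seq(0, 1,
                                                     length.out = nBins + 1)))
        if (length(qs) < 2L) b[pos] <- 1L
        else b[pos] <- as.integer(cut(xp, breaks = qs, include.lowest = TRUE))
    }
    b
}

#' Plug-in mutual information with zero-aware binning
#'
#' Each vector is discretized with zeros kept as their own category and
#' positive values split into equal-frequency bins (default 5); mutual
#' information of the joint histogram is returned in nats.  The zero bin
#' preserves the occurrence signal that quantile binning alone would
#' smear in zero-inflated data.
#'
#' @inheritParams phiCoefficient
#' @param nBins number of equal-frequency bins for the positive part.
#' @return mutual information in nats (non-negative).
#' @examples
#' mutualInformation(rpois(100, 3), rpois(100, 3))
#' @export
mutualInformation <- function(x, y, nBins = 5) {
    stopifnot(length(x) == length(y))
    bx <- .binZeroQuantile(x, nBins)
    by <- .binZeroQuantile(y, nBins)
    tab <- table(bx, by) / length(x)
    px <- rowSums(tab); py <- colSums(tab)
    e <- outer(px, py)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / e[nz]))
}

#' Maximal information coefficient (MIC)
#'
#' Grid-search estimate of the maximal information coefficient with grid
#' bound \eqn{B(n) = n^{0.6}}: over every grid shape \eqn{(n_x, n_y)} with
#' \eqn{n_x n_y \le B(n)}, one axis is equipartitioned and the other
#' optimized by dynamic programming over tie-respecting candidate cut
#' points; the maximum of \eqn{MI / \log_2 \min(n_x, n_y)} over shapes and
#' both orientations is returned.  Values lie in [0, 1]; 1 for a strictly
#' monotone noiseless relationship.
#'
#' @inheritParams phiCoefficient
#' @param alpha exponent of the grid-size bound (default 0.6).
#' @param clumpFactor controls how many candidate cut points the optimized
#'   axis keeps per allowed bin (default 5); larger values search more
#'   partitions at higher cost.
#' @return the MIC in [0, 1], or NA if either vector is constant or too
#'   short.
#' @examples
#' x <- sort(runif(50)); micStat(x, x^3)  # 1: monotone, no ties
#' @export
micStat <- function(x, y, alpha = 0.6, clumpFactor = 5) {
    stopifnot(length(x) == length(y))
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
        warning("MIC undefined: constant vector", call. = FALSE)
        return(NA_real_)
    }
    .micCpp(as.numeric(x), as.numeric(y), alpha, as.integer(clumpFactor))
}

#' Compute one association measure between two OTU count vectors
#'
#' Unified front end over the six supported measures.  Pearson and
#' Spearman are the standard estimators (\code{stats::cor}; Spearman uses
#' mid-ranks for the pervasive ties at zero).
#'
#' @inheritParams phiCoefficient
#' @param measure one of \code{"pearson"}, \code{"spearman"},
#'   \code{"phi"}, \code{"bray_curtis"}, \code{"mutual_information"},
#'   \code{"mic"}.
#' @param ... passed to the individual measure (e.g. \code{nBins}).
#' @return a list with \code{value}, \code{measure} and \code{n} (samples
#'   used).
#' @examples
#' associationMeasure(rpois(30, 5), rpois(30, 5), "spearman")
#' @export
associationMeasure <- function(x, y,
                               measure = c("pearson", "spearman", "phi",
                                           "bray_curtis",
                                           "mutual_information", "mic"),
                               ...) {
    measure <- match.arg(measure)
    value <- switch(measure,
        pearson = if (stats::sd(x) == 0 || stats::sd(y) == 0) {
            warning("correlation undefined: constant vector", call. = FALSE)
            NA_real_
        } else stats::cor(x, y),
        spearman = if (stats::sd(x) == 0 || stats::sd(y) == 0) {
            warning("correlation undefined: constant vector", call. = FALSE)
            NA_real_
        } else stats::cor(x, y, method = "spearman"),
        phi = phiCoefficient(x, y),
        bray_curtis = brayCurtis(x, y),
        mutual_information = mutualInformation(x, y, ...),
        mic = micStat(x, y, ...))
    list(value = value, measure = measure, n = length(x))
}

#' Pairwise association measures over an OTU table
#'
#' @param counts OTU-by-sample count matrix or SummarizedExperiment.
#' @param measures character vector of measures, see
#'   \code{\link{associationMeasure}}.
#' @param ... passed to the individual measures.
#' @return long-format data.frame (otu_i, otu_j, measure, value).
#' @export
measureTable <- function(counts, measures = "spearman", ...) {
    if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
    p <- nrow(counts)
    nm <- rownames(counts) %||% paste0("OTU", seq_len(p))
    idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
    out <- lapply(measures, function(m) {
        vals <- suppressWarnings(vapply(seq_len(nrow(idx)), function(r)
            associationMeasure(counts[idx[r, 1L], ], counts[idx[r, 2L], ],
                               m, ...)$value, 0))
        data.frame(otu_i = nm[idx[, 1L]], otu_j = nm[idx[, 2L]],
                   measure = m, value = vals)
    })
    do.call(rbind, out)
}
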