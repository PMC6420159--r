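#' Centered log-ratio transform
#'
#' Per sample (row): \eqn{\log(x + c)} minus the mean of the same, so
#' every transformed sample sums to zero.  The pseudocount \eqn{c}
#' (default 1) handles the pervasive zeros of OTU tables; for all-positive
#' data the transform becomes exactly compositionally invariant as
#' \eqn{c \to 0}.
#'
#' @param counts samples-by-OTUs numeric matrix.
#' @param pseudocount positive offset added before taking logs.
#' @return matrix of the same shape; rows sum to zero.
#' @examples
#' z <- clrTransform(matrix(rpois(20, 10), 4, 5))
#' rowSums(z)
#' @export
clrTransform <- function(counts, pseudocount = 1) {
    stopifnot(pseudocount > 0, all(counts >= 0))
    lg <- log(counts + pseudocount)
    sweep(lg, 1L, rowMeans(lg))
}

.geometricPath <- function(S, nPenalties = 20, ratio = 0.1) {
    lamMax <- max(abs(S[upper.tri(S)]))
    if (!is.finite(lamMax) || lamMax <= 0) lamMax <- 1
    exp(seq(log(lamMax), log(lamMax * ratio), length.out = nPenalties))
}

#' Graphical lasso with per-pair penalty masking
#'
#' L1-penalized precision-matrix estimation on the sample correlation of
#' \code{x}, with an element-wise penalty matrix: the base penalty
#' everywhere and \code{maskFactor} times the base penalty on masked
#' pairs, which drives their precision entries to exactly zero - the
#' mechanism by which non-testable pairs are excluded from inference
#' while the rest of the problem is estimated jointly.
#'
#' @param x an n-by-p data matrix (rows = samples; standardized to a
#'   correlation matrix internally), or a p-by-p correlation matrix with
#'   \code{isCorrelation = TRUE}.
#' @param penalty base L1 penalty (scalar, positive).
#' @param mask optional logical p-by-p matrix (TRUE = masked pair) or a
#'   \code{\linkS4class{TestabilityMask}}, whose problematic (not fully
#'   testable) pairs are masked.
#' @param maskFactor penalty multiplier on masked pairs (default 1e3,
#'   effectively infinite).
#' @param isCorrelation set TRUE when \code{x} is already a correlation
#'   matrix.
#' @param maxIter,tol outer-loop iteration cap and convergence tolerance
#'   (relative to the mean absolute off-diagonal correlation).
#' @param warmStart optional list with elements \code{W} and \code{B}
#'   from a previous fit at a nearby penalty (path acceleration).
#' @return a list with \code{precision} (p x p), \code{partialCor}
#'   (the matrix of partial correlations \eqn{-\theta_{ij}/
#'   \sqrt{\theta_{ii}\theta_{jj}}}), \code{penalty}, \code{converged},
#'   \code{iterations}, and \code{W}, \code{B} for warm starts.
#'   Non-convergence gives a warning, not an error.
#' @examples
#' x <- MASS::mvrnorm(200, rep(0, 5), diag(5))
#' fit <- graphicalLassoMasked(x, penalty = 0.2)
#' @export
graphicalLassoMasked <- function(x, penalty, mask = NULL, maskFactor = 1e3,
                                 isCorrelation = FALSE, maxIter = 100,
                                 tol = 1e-4, warmStart = NULL) {
    stopifnot(length(penalty) == 1L, penalty >= 0)
    S <- if (isCorrelation) x else stats::cor(x)
    p <- ncol(S)
    Rho <- matrix(penalty, p, p)
    if (!is.null(mask)) {
        if (is(mask, "TestabilityMask")) mask <- problematicPairs(mask)
        stopifnot(all(dim(mask) == p))
        mm <- mask; mm[is.na(mm)] <- FALSE
        Rho[mm] <- penalty * maskFactor
        diag(Rho) <- penalty
    }
    warm <- !is.null(warmStart)
    W0 <- if (warm) warmStart$W else matrix(0, p, p)
    B0 <- if (warm) warmStart$B else matrix(0, p, p)
    fit <- .glassoCpp(S, Rho, W0, B0, as.integer(maxIter), tol, warm)
    if (!fit$converged)
        warning(sprintf("graphical lasso did not converge in %d sweeps ",
                        maxIter), "(penalty=", signif(penalty, 3), ")",
                call. = FALSE)
    Theta <- fit$precision
    d <- sqrt(diag(Theta))
    pc <- -Theta / outer(d, d)
    diag(pc) <- 1
    list(precision = Theta, partialCor = pc, penalty = penalty,
         converged = fit$converged, iterations = fit$iterations,
         W = fit$W, B = fit$B)
}

#' Prevalence-based OTU filter matched to a target pair count
#'
#' Greedily removes the lowest-prevalence OTUs (ties broken by OTU index,
#' deterministically) until the number of removed OTU pairs is at least
#' \code{targetFilteredPairs} - the conventional-filter baseline matched
#' in severity to testability-based filtering.
#'
#' @param prevalences per-OTU prevalence vector.
#' @param targetFilteredPairs minimum number of pairs the filter must
#'   remove.
#' @return integer vector of kept OTU indices (sorted), with attribute
#'   \code{nFilteredPairs}.
#' @examples
#' prevalenceFilter(c(0.1, 0.9, 0.2, 0.8), targetFilteredPairs = 3)
#' @export
prevalenceFilter <- function(prevalences, targetFilteredPairs) {
    p <- length(prevalences)
    totalPairs <- choose(p, 2L)
    stopifnot(targetFilteredPairs >= 0, targetFilteredPairs <= totalPairs)
    if (targetFilteredPairs == 0) {
        out <- seq_len(p)
        attr(out, "nFilteredPairs") <- 0
        return(out)
    }
    ord <- order(prevalences, seq_len(p))
    m <- 0L
    while (totalPairs - choose(p - m, 2L) < targetFilteredPairs) m <- m + 1L
    kept <- sort(ord[-seq_len(m)])
    attr(kept, "nFilteredPairs") <- totalPairs - choose(p - m, 2L)
    kept
}

#' Infer a signed association network with optional testability masking
#'
#' The full inference pipeline: centered log-ratio transform, then
#' stability selection over random subsamples and a geometric penalty
#' path of masked graphical lasso fits.  Each unordered OTU pair is
#' scored by its selection frequency (fraction of subsample-by-penalty
#' fits in which its precision entry is non-zero) signed by the direction
#' of its average partial correlation.  Depending on
#' \code{filterMode}, non-testable pairs are masked inside the estimator
#' (\code{"testability"}), low-prevalence OTUs are dropped to match the
#' testability filter's severity (\code{"prevalence"}), or nothing is
#' filtered (\code{"none"}).  Masked pairs carry score exactly 0 and are
#' flagged so evaluation can exclude them.
#'
#' @param x a samples-by-OTUs count matrix, or a
#'   \code{\linkS4class{SimulatedCommunity}} /
#'   \code{SummarizedExperiment} (whose \code{"counts"} assay is
#'   OTUs-by-samples).
#' @param filterMode \code{"none"}, \code{"testability"} or
#'   \code{"prevalence"}.
#' @param alpha significance level for the testability mask.
#' @param maskMode classifier behind the mask (default
#'   \code{"abundance"}, matching clr-based abundance inference).
#' @param penaltyPath decreasing positive penalties; \code{NULL} builds a
#'   geometric path of \code{nPenalties} values from the largest absolute
#'   off-diagonal correlation down to \code{pathRatio} times it.
#' @param nPenalties,pathRatio geometry of the default path.
#' @param pseudocount clr pseudocount.
#' @param subsampleFraction,repetitions stability-selection subsample
#'   fraction (default 0.8) and number of subsamples (default 50).
#' @param maskFactor penalty multiplier on masked pairs.
#' @param rngSeed integer seed for the subsample draws.
#' @param targetFilteredPairs pair-removal target for
#'   \code{filterMode = "prevalence"}; defaults to the number of
#'   problematic pairs of the testability mask at the same alpha.
#' @param ... passed between methods.
#' @return an \code{\linkS4class{EdgeScores}} object.
#' @examples
#' sim <- simulateCommunity(15, 80, nEdges = 6, prevalence = 0.9,
#'                          conditionTarget = 10, rngSeed = 1)
#' sc <- inferNetwork(sim, repetitions = 10, rngSeed = 2)
#' @rdname inferNetwork
#' @export
setMethod("inferNetwork", "matrix",
    function(x, filterMode = c("none", "testability", "prevalence"),
             alpha = 0.05, maskMode = "abundance", penaltyPath = NULL,
             nPenalties = 20, pathRatio = 0.1, pseudocount = 1,
             subsampleFraction = 0.8, repetitions = 50, maskFactor = 1e3,
             rngSeed, targetFilteredPairs = NULL, ...) {
    filterMode <- match.arg(filterMode)
    n <- nrow(x); p <- ncol(x)
    otuIds <- colnames(x) %||% paste0("OTU", seq_len(p))
    prev <- colMeans(x > 0)

    maskMat <- matrix(FALSE, p, p)
    if (filterMode == "testability") {
        tm <- suppressWarnings(testabilityMask(prev, n = n, alpha = alpha,
                                               mode = maskMode))
        maskMat <- problematicPairs(tm)
        maskMat[is.na(maskMat)] <- FALSE
    } else if (filterMode == "prevalence") {
        if (is.null(targetFilteredPairs)) {
            tm <- suppressWarnings(testabilityMask(prev, n = n,
                                                   alpha = alpha,
                                                   mode = maskMode))
            pp <- problematicPairs(tm)
            targetFilteredPairs <- sum(pp[upper.tri(pp)], na.rm = TRUE)
        }
        kept <- prevalenceFilter(prev, targetFilteredPairs)
        dropped <- setdiff(seq_len(p), kept)
        maskMat[dropped, ] <- TRUE
        maskMat[, dropped] <- TRUE
    }
    diag(maskMat) <- FALSE

    z <- clrTransform(x, pseudocount)
    if (is.null(penaltyPath))
        penaltyPath <- .geometricPath(stats::cor(z), nPenalties, pathRatio)
    if (length(penaltyPath) == 0L)
        stop("empty penalty path", call. = FALSE)
    penaltyPath <- sort(penaltyPath, decreasing = TRUE)

    nSub <- max(3L, floor(subsampleFraction * n))
    subsets <- .withSeed(rngSeed, lapply(seq_len(repetitions), function(r)
        sample.int(n, nSub)))

    selCount <- matrix(0, p, p)
    pcSum <- matrix(0, p, p)
    nFits <- 0L
    for (r in seq_len(repetitions)) {
        S <- stats::cor(z[subsets[[r]], , drop = FALSE])
        warm <- NULL
        for (lam in penaltyPath) {
            fit <- suppressWarnings(graphicalLassoMasked(
                S, penalty = lam, mask = maskMat, maskFactor = maskFactor,
                isCorrelation = TRUE, warmStart = warm))
            warm <- fit[c("W", "B")]
            sel <- abs(fit$precision) > 1e-7
            diag(sel) <- FALSE
            selCount <- selCount + sel
            pcSum <- pcSum + fit$partialCor * sel
            nFits <- nFits + 1L
        }
    }
    freq <- selCount / nFits
    sgn <- sign(pcSum)
    score <- freq * sgn
    score[maskMat] <- 0

    idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
    pairs <- data.frame(i = idx[, 1L], j = idx[, 2L],
                        otu_i = otuIds[idx[, 1L]], otu_j = otuIds[idx[, 2L]],
                        score = score[idx], masked = maskMat[idx])
    new("EdgeScores", pairs = pairs, nOtus = as.integer(p),
        config = list(filterMode = filterMode, alpha = alpha,
                      maskMode = maskMode, penaltyPath = penaltyPath,
                      pseudocount = pseudocount,
                      subsampleFraction = subsampleFraction,
                      repetitions = repetitions, maskFactor = maskFactor,
                      rngSeed = rngSeed,
                      nMaskedPairs = sum(pairs$masked)))
})

#' @rdname inferNetwork
#' @export
setMethod("inferNetwork", "SummarizedExperiment", function(x, ...) {
    inferNetwork(t(assay(x, "counts")), ...)
})
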