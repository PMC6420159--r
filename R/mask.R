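#' Pairwise testability mask over a set of OTUs
#'
#' Applies one of the per-pair testability classifiers
#' (\code{\link{classifyOccurrence}}, \code{\link{fisherTestability}},
#' \code{\link{classifyAbundance}}) to every unordered pair of OTUs and
#' assembles the verdicts into a symmetric
#' \code{\linkS4class{TestabilityMask}}.  Degenerate OTUs (prevalence 0
#' or 1, for which no association is estimable) are flagged with a warning
#' and marked non-testable for every pair rather than raising an error.
#'
#' For \code{mode = "occurrence_fisher"} prevalences are converted to
#' occupancy counts as \code{round(p * n)}; conversions hitting 0 or
#' \code{n} are treated as degenerate.
#'
#' @param x per-OTU prevalences (numeric vector in [0, 1]), an OTU-by-sample
#'   count matrix, or a \code{SummarizedExperiment} with a \code{"counts"}
#'   assay (prevalence is then computed per OTU as the fraction of samples
#'   with a non-zero count).
#' @param n sample count; defaulted to the number of samples when \code{x}
#'   carries counts.
#' @param alpha significance level.
#' @param mode \code{"occurrence_phi"} (chi-squared/Phi rule),
#'   \code{"occurrence_fisher"} (hypergeometric enumeration) or
#'   \code{"abundance"} (Student/Pearson rule).
#' @param ... passed between methods.
#' @return a \code{\linkS4class{TestabilityMask}}.
#' @examples
#' testabilityMask(c(0.02, 0.02, 0.5), n = 50, mode = "occurrence_phi")
#' @rdname testabilityMask
#' @export
setMethod("testabilityMask", "numeric",
    function(x, n, alpha = 0.05,
             mode = c("occurrence_phi", "occurrence_fisher", "abundance"),
             ...) {
    mode <- match.arg(mode)
    .checkSettings(n, alpha)
    if (anyNA(x) || any(x < 0 | x > 1))
        stop("prevalences must lie in [0, 1]", call. = FALSE)
    p <- length(x)
    if (p < 2L) stop("need at least two OTUs", call. = FALSE)
    degen <- x <= 0 | x >= 1
    if (mode == "occurrence_fisher") {
        cnt <- round(x * n)
        degen <- degen | cnt <= 0 | cnt >= n
    }
    if (any(degen))
        warning(sum(degen), " OTU(s) with degenerate prevalence (0 or 1);",
                " marked non-testable for every pair", call. = FALSE)
    pos <- neg <- matrix(FALSE, p, p)
    ok <- which(!degen)
    if (length(ok) >= 2L) {
        idx <- which(upper.tri(diag(length(ok))), arr.ind = TRUE)
        i <- ok[idx[, 1L]]; j <- ok[idx[, 2L]]
        v <- switch(mode,
            occurrence_phi = classifyOccurrence(x[i], x[j], n, alpha),
            occurrence_fisher = fisherTestability(round(x[i] * n),
                                                  round(x[j] * n), n, alpha),
            abundance = classifyAbundance(x[i], x[j], n, alpha))
        pos[cbind(i, j)] <- v$positive_testable
        pos[cbind(j, i)] <- v$positive_testable
        neg[cbind(i, j)] <- v$negative_testable
        neg[cbind(j, i)] <- v$negative_testable
    }
    diag(pos) <- diag(neg) <- NA
    nm <- names(x) %||% paste0("OTU", seq_len(p))
    dimnames(pos) <- dimnames(neg) <- list(nm, nm)
    new("TestabilityMask", positive = pos, negative = neg,
        prevalence = unname(x), nSamples = as.integer(n), alpha = alpha,
        mode = mode, degenerate = unname(degen))
})

#' @rdname testabilityMask
#' @export
setMethod("testabilityMask", "matrix",
    function(x, n = ncol(x), alpha = 0.05,
             mode = c("occurrence_phi", "occurrence_fisher", "abundance"),
             ...) {
    prev <- prevalenceVector(x)
    testabilityMask(prev, n = n, alpha = alpha, mode = mode)
})

#' @rdname testabilityMask
#' @export
setMethod("testabilityMask", "SummarizedExperiment",
    function(x, n = ncol(x), alpha = 0.05,
             mode = c("occurrence_phi", "occurrence_fisher", "abundance"),
             ...) {
    testabilityMask(prevalenceVector(x), n = n, alpha = alpha, mode = mode)
})

#' Per-OTU prevalence
#'
#' Prevalence of an OTU is the number of samples in which it has a non-zero
#' count divided by the total number of samples.
#'
#' @param x an OTU-by-sample count matrix or a \code{SummarizedExperiment}
#'   with a \code{"counts"} assay.
#' @param ... unused.
#' @return named numeric vector of prevalences in [0, 1], one per OTU.
#' @examples
#' prevalenceVector(rbind(a = c(0, 3, 5, 0), b = c(1, 1, 0, 2)))
#' @rdname prevalenceVector
#' @export
setMethod("prevalenceVector", "matrix", function(x, ...) {
    if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
    rowMeans(x > 0)
})

#' @rdname prevalenceVector
#' @export
setMethod("prevalenceVector", "SummarizedExperiment", function(x, ...) {
    prevalenceVector(assay(x, "counts"))
})

setMethod("maskCategories", "TestabilityMask",
    function(x, encoded = FALSE, ...) {
    p <- length(x@prevalence)
    out <- matrix(.category(as.vector(x@positive), as.vector(x@negative)),
                  p, p, dimnames = dimnames(x@positive))
    out[is.na(x@positive)] <- NA
    if (encoded) {
        enc <- matrix(.CATEGORY_CODES[out], p, p,
                      dimnames = dimnames(out))
        return(enc)
    }
    out
})

setMethod("positiveTestable", "TestabilityMask", function(x) x@positive)
setMethod("negativeTestable", "TestabilityMask", function(x) x@negative)

setMethod("problematicPairs", "TestabilityMask", function(x) {
    out <- !(x@positive & x@negative)
    diag(out) <- NA
    out
})

#' Long-format edge list of a testability mask or edge scores
#'
#' @param x a \code{\linkS4class{TestabilityMask}} or
#'   \code{\linkS4class{EdgeScores}}.
#' @param ... unused.
#' @return a data.frame with one row per unordered OTU pair.
#' @rdname edgeTable
#' @export
setMethod("edgeTable", "TestabilityMask", function(x, ...) {
    p <- length(x@prevalence)
    idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
    nm <- rownames(x@positive)
    data.frame(otu_i = nm[idx[, 1L]], otu_j = nm[idx[, 2L]],
               positive_testable = x@positive[idx],
               negative_testable = x@negative[idx],
               category = maskCategories(x)[idx])
})

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "EdgeScores", function(x, ...) x@pairs)

setMethod("truthAdjacency", "SimulatedCommunity",
          function(x) metadata(x)$truth)
setMethod("latentCorrelation", "SimulatedCommunity",
          function(x) metadata(x)$correlation)
setMethod("targetPrevalence", "SimulatedCommunity",
          function(x) rowData(x)$targetPrevalence)
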