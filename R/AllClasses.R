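#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata SimpleList DataFrame
NULL

.CATEGORY_CODES <- c(full = 2L, positive_only = 1L, negative_only = -1L,
                     none = 0L)

#' TestabilityMask: pairwise testability verdicts for a set of OTUs
#'
#' A symmetric OTU-by-OTU container of testability verdicts, produced by
#' \code{\link{testabilityMask}}.  Each off-diagonal entry records whether a
#' positive and whether a negative association between the two OTUs could
#' ever reach significance at the stored sample size and alpha level, given
#' their prevalences.  The diagonal is not applicable and is stored as
#' \code{NA}.
#'
#' @slot positive logical matrix; \code{[i, j]} is \code{TRUE} when a
#'   positive association between OTUs i and j is testable.
#' @slot negative logical matrix; likewise for negative associations.
#' @slot prevalence numeric vector of per-OTU prevalences used.
#' @slot nSamples integer sample count.
#' @slot alpha significance level.
#' @slot mode one of \code{"occurrence_phi"}, \code{"occurrence_fisher"},
#'   \code{"abundance"}.
#' @slot degenerate logical vector flagging OTUs with prevalence 0 or 1,
#'   which are excluded (marked non-testable for every pair).
#' @seealso \code{\link{testabilityMask}}, \code{\link{maskCategories}},
#'   \code{\link{problematicPairs}}
#' @exportClass TestabilityMask
setClass("TestabilityMask",
    representation(positive = "matrix", negative = "matrix",
                   prevalence = "numeric", nSamples = "integer",
                   alpha = "numeric", mode = "character",
                   degenerate = "logical"),
    validity = function(object) {
        p <- length(object@prevalence)
        msg <- character()
        if (!all(dim(object@positive) == c(p, p)) ||
            !all(dim(object@negative) == c(p, p)))
            msg <- c(msg, "verdict matrices must be nOTU x nOTU")
        else {
            if (!isTRUE(all.equal(object@positive,
                                  t(object@positive))) ||
                !isTRUE(all.equal(object@negative, t(object@negative))))
                msg <- c(msg, "verdict matrices must be symmetric")
            if (!all(is.na(diag(object@positive))))
                msg <- c(msg, "diagonal must be NA (not applicable)")
        }
        if (!object@mode %in% c("occurrence_phi", "occurrence_fisher",
                                "abundance"))
            msg <- c(msg, "unknown mode")
        if (length(object@degenerate) != p)
            msg <- c(msg, "degenerate flag length must match prevalence")
        if (length(msg)) msg else TRUE
    })

#' SimulatedCommunity: copula-simulated counts with known association truth
#'
#' Extends \code{SummarizedExperiment}: the \code{"counts"} assay holds the
#' simulated OTU-by-sample count matrix, \code{rowData} carries per-OTU
#' generating parameters (target structural prevalence, marginal mean and
#' dispersion), and \code{metadata} stores the ground-truth signed adjacency
#' (\code{truth}), the latent generating correlation matrix
#' (\code{correlation}), its condition number, and the seeds used.
#'
#' @seealso \code{\link{simulateCommunity}}, \code{\link{truthAdjacency}},
#'   \code{\link{latentCorrelation}}
#' @exportClass SimulatedCommunity
setClass("SimulatedCommunity", contains = "SummarizedExperiment",
    validity = function(object) {
        md <- metadata(object)
        msg <- character()
        p <- nrow(object)
        if (is.null(md$truth) || !all(dim(md$truth) == c(p, p)))
            msg <- c(msg, "metadata()$truth must be a p x p signed adjacency")
        else {
            if (!all(md$truth %in% c(-1L, 0L, 1L)))
                msg <- c(msg, "truth entries must be -1, 0 or +1")
            if (any(diag(md$truth) != 0L))
                msg <- c(msg, "truth diagonal must be zero")
            if (!isTRUE(all.equal(md$truth, t(md$truth))))
                msg <- c(msg, "truth must be symmetric")
        }
        if (is.null(md$correlation) || !all(dim(md$correlation) == c(p, p)))
            msg <- c(msg, "metadata()$correlation must be p x p")
        if (length(msg)) msg else TRUE
    })

#' EdgeScores: signed per-pair association scores from network inference
#'
#' Holds one row per unordered OTU pair: a signed score whose magnitude is
#' the stability-selection confidence and whose sign is the direction of
#' the average partial correlation, plus a \code{masked} flag for pairs
#' excluded by filtering (their score is exactly 0 and they are excluded
#' from evaluation denominators).
#'
#' @slot pairs data.frame with columns \code{i}, \code{j} (1-based OTU
#'   indices, i < j), \code{otu_i}, \code{otu_j} (ids), \code{score},
#'   \code{masked}.
#' @slot nOtus integer number of OTUs scored.
#' @slot config list: the inference configuration and seeds.
#' @seealso \code{\link{inferNetwork}}, \code{\link{signedAuc}}
#' @exportClass EdgeScores
setClass("EdgeScores",
    representation(pairs = "data.frame", nOtus = "integer", config = "list"),
    validity = function(object) {
        need <- c("i", "j", "otu_i", "otu_j", "score", "masked")
        msg <- character()
        if (!all(need %in% names(object@pairs)))
            msg <- c(msg, paste("pairs must have columns:",
                                paste(need, collapse = ", ")))
        else {
            pr <- object@pairs
            if (nrow(pr) != choose(object@nOtus, 2L))
                msg <- c(msg, "pairs must enumerate all unordered OTU pairs")
            if (any(pr$i >= pr$j))
                msg <- c(msg, "pair indices must satisfy i < j")
            if (any(pr$masked & pr$score != 0))
                msg <- c(msg, "masked pairs must carry score exactly 0")
        }
        if (length(msg)) msg else TRUE
    })

setMethod("show", "TestabilityMask", function(object) {
    p <- length(object@prevalence)
    cat(sprintf("TestabilityMask: %d OTUs, mode=%s, n=%d, alpha=%g\n",
                p, object@mode, object@nSamples, object@alpha))
    tab <- table(factor(maskCategories(object)[upper.tri(diag(p))],
                        levels = names(.CATEGORY_CODES)))
    cat("  pair categories:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    if (any(object@degenerate))
        cat("  degenerate OTUs (prevalence 0 or 1):",
            sum(object@degenerate), "\n")
})

setMethod("show", "SimulatedCommunity", function(object) {
    callNextMethod()
    tr <- truthAdjacency(object)
    up <- tr[upper.tri(tr)]
    cat(sprintf("truth: %d positive, %d negative edges; cond(correlation)=%.2f\n",
                sum(up == 1L), sum(up == -1L),
                metadata(object)$conditionNumber))
})

setMethod("show", "EdgeScores", function(object) {
    pr <- object@pairs
    cat(sprintf("EdgeScores: %d OTUs, %d pairs (%d masked), filter=%s\n",
                object@nOtus, nrow(pr), sum(pr$masked),
                object@config$filterMode %||% "none"))
    cat(sprintf("  nonzero scores: %d, score range [%.3f, %.3f]\n",
                sum(pr$score != 0), min(pr$score), max(pr$score)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
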