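#' Sign-resolved AUC and AUPRC of edge recovery
#'
#' Evaluates how well the signed edge scores rank true associations of one
#' sign above everything else, over the candidate (unmasked) pairs only.
#' For \code{sign = "positive"} the labels are the true positive edges and
#' pairs are ranked by \code{+score}; for \code{sign = "negative"} the
#' labels are the true negative edges and pairs are ranked by
#' \code{-score}.  AUC is computed by the Mann-Whitney rank identity
#' (mid-ranks for ties); AUPRC by step-interpolated precision-recall
#' (average precision), which avoids the optimistic bias of trapezoidal
#' interpolation over precision.
#'
#' @param scores an \code{\linkS4class{EdgeScores}} object.
#' @param truth signed adjacency matrix (-1/0/+1) or a
#'   \code{\linkS4class{SimulatedCommunity}}.
#' @param sign \code{"positive"} or \code{"negative"}.
#' @return a list with \code{auc}, \code{auprc}, \code{nCandidates},
#'   \code{nTrueEdges}; both metrics are NA (with a warning) when no true
#'   edge of the requested sign survives among the candidates.
#' @examples
#' sim <- simulateCommunity(10, 60, nEdges = 5, prevalence = 0.9,
#'                          conditionTarget = 10, rngSeed = 1)
#' sc <- inferNetwork(sim, repetitions = 5, rngSeed = 2)
#' signedAuc(sc, sim, "positive")
#' @export
signedAuc <- function(scores, truth, sign = c("positive", "negative")) {
    sign <- match.arg(sign)
    if (is(truth, "SimulatedCommunity")) truth <- truthAdjacency(truth)
    pr <- edgeTable(scores)
    stopifnot(all(dim(truth) == scores@nOtus))
    truthVec <- truth[cbind(pr$i, pr$j)]
    keep <- !pr$masked
    lab <- if (sign == "positive") truthVec[keep] == 1L else
        truthVec[keep] == -1L
    rk <- if (sign == "positive") pr$score[keep] else -pr$score[keep]
    nPos <- sum(lab); nNeg <- sum(!lab)
    if (nPos == 0L || nNeg == 0L) {
        warning("no true edges of sign '", sign,
                "' among candidate pairs: AUC undefined", call. = FALSE)
        return(list(auc = NA_real_, auprc = NA_real_,
                    nCandidates = sum(keep), nTrueEdges = nPos))
    }
    r <- rank(rk)                     # mid-ranks for ties
    auc <- (sum(r[lab]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)

    # average precision with tied scores processed as one threshold group
    ord <- order(rk, decreasing = TRUE)
    labOrd <- lab[ord]; rkOrd <- rk[ord]
    grp <- cumsum(!duplicated(rkOrd))
    tpByGrp <- tapply(labOrd, grp, sum)
    szByGrp <- tapply(labOrd, grp, length)
    tp <- cumsum(tpByGrp); fp <- cumsum(szByGrp) - tp
    prec <- tp / (tp + fp)
    dRecall <- diff(c(0, tp)) / nPos
    auprc <- sum(prec * dRecall)

    list(auc = auc, auprc = auprc, nCandidates = sum(keep),
         nTrueEdges = nPos)
}

.benchRow <- function(condition, sgn, ev, extra = list()) {
    cbind(data.frame(condition = condition, sign = sgn, auc = ev$auc,
                     auprc = ev$auprc, nCandidatePairs = ev$nCandidates,
                     nTrueEdges = ev$nTrueEdges),
          as.data.frame(extra))
}

#' Prevalence sweep benchmark of network inference
#'
#' The constant-prevalence experiment: communities with a fixed signed
#' association structure are simulated over a grid of shared OTU
#' prevalences (default 20 logarithmic steps from 0.05 to 1), inference
#' is run without filtering, and sign-resolved AUC/AUPRC are recorded.
#' Detection of negative associations collapses as prevalence drops,
#' while positive associations degrade more slowly.
#'
#' @param prevalenceLevels prevalences to scan.
#' @param nSims simulations per level.
#' @param nOtus,nSamples,nEdges,conditionTarget community specification
#'   (defaults: 100 OTUs, 50 samples, 100 edges half positive, condition
#'   number 100).
#' @param rngSeed integer seed.
#' @param ... inference options passed to \code{\link{inferNetwork}}
#'   (e.g. \code{repetitions}, \code{nPenalties}).
#' @return data.frame with one row per (level, simulation, sign),
#'   including the realized mean prevalence of each simulated dataset.
#' @export
prevalenceSweepBenchmark <- function(prevalenceLevels =
                                         exp(seq(log(0.05), log(1),
                                                 length.out = 20)),
                                     nSims = 20, nOtus = 100, nSamples = 50,
                                     nEdges = 100, conditionTarget = 100,
                                     rngSeed, ...) {
    rows <- list()
    for (li in seq_along(prevalenceLevels)) {
        lev <- min(prevalenceLevels[li], 1 - 1e-9)
        for (s in seq_len(nSims)) {
            seed <- rngSeed + 7919L * li + s
            sim <- simulateCommunity(nOtus, nSamples, nEdges,
                                     conditionTarget = conditionTarget,
                                     prevalence = lev, rngSeed = seed)
            sc <- inferNetwork(sim, filterMode = "none",
                               rngSeed = seed + 1L, ...)
            for (sg in c("positive", "negative")) {
                ev <- suppressWarnings(signedAuc(sc, sim, sg))
                rows[[length(rows) + 1L]] <- .benchRow(
                    sprintf("prevalence=%.3f", lev), sg, ev,
                    list(prevalence = prevalenceLevels[li], sim = s,
                         realizedPrevalence =
                             mean(prevalenceVector(sim)),
                         seed = seed))
            }
        }
    }
    do.call(rbind, rows)
}

#' Filtering benchmark: none vs testability vs prevalence filtering
#'
#' The data-filtering experiment: power-law-prevalence communities are
#' simulated, the fraction of problematic (not fully testable) pairs is
#' recorded, and the network is inferred under each filtering mode; edge
#' recovery is evaluated by sign over the pairs surviving each filter.
#'
#' @param nOtus,nSamples,nEdges,k,pMin,conditionTarget community
#'   specification (defaults: the 300-sample, 300-OTU, 1000-edge,
#'   k = -1.5 configuration with minimum prevalence 5/300).
#' @param modes filtering modes to compare.
#' @param nSims number of simulations.
#' @param alpha significance level of the testability mask.
#' @param scale factor in (0, 1] shrinking the community for desk-scale
#'   runs: the OTU count is multiplied by \code{scale} and the edge count
#'   is reduced proportionally to the number of pairs, preserving edge
#'   density, k, alpha and the condition number.
#' @param rngSeed integer seed.
#' @param ... inference options passed to \code{\link{inferNetwork}}.
#' @return data.frame with one row per (simulation, mode, sign); the
#'   column \code{problematicFraction} carries the per-simulation
#'   fraction of not-fully-testable pairs.
#' @export
filteringBenchmark <- function(nOtus = 300, nSamples = 300, nEdges = 1000,
                               k = -1.5, pMin = 5 / 300,
                               conditionTarget = 100,
                               modes = c("none", "testability",
                                         "prevalence"),
                               nSims = 20, alpha = 0.05, scale = 1,
                               rngSeed, ...) {
    stopifnot(scale > 0, scale <= 1)
    p <- max(10L, round(nOtus * scale))
    e <- max(2L, round(nEdges * choose(p, 2L) / choose(nOtus, 2L)))
    rows <- list()
    for (s in seq_len(nSims)) {
        seed <- rngSeed + 104729L * s
        sim <- simulateCommunity(p, nSamples, e,
                                 conditionTarget = conditionTarget,
                                 prevalence = list(k = k, pMin = pMin),
                                 rngSeed = seed)
        prev <- prevalenceVector(sim)
        tm <- suppressWarnings(testabilityMask(prev, n = nSamples,
                                               alpha = alpha,
                                               mode = "abundance"))
        ppm <- problematicPairs(tm)
        probFrac <- mean(ppm[upper.tri(ppm)], na.rm = TRUE)
        for (mode in modes) {
            sc <- inferNetwork(sim, filterMode = mode, alpha = alpha,
                               rngSeed = seed + 1L, ...)
            for (sg in c("positive", "negative")) {
                ev <- suppressWarnings(signedAuc(sc, sim, sg))
                rows[[length(rows) + 1L]] <- .benchRow(mode, sg, ev,
                    list(sim = s, problematicFraction = probFrac,
                         nOtus = p, nEdges = e, seed = seed))
            }
        }
    }
    do.call(rbind, rows)
}
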