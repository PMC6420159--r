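#' @useDynLib AssocTestability, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.checkPrevalence <- function(p, argname = "prevalence") {
    if (!is.numeric(p) || anyNA(p))
        stop(argname, " must be numeric and non-missing", call. = FALSE)
    if (any(p <= 0 | p >= 1))
        stop(argname, " must lie strictly between 0 and 1 ",
             "(prevalence 0 or 1 is degenerate)", call. = FALSE)
    invisible(p)
}

.checkSettings <- function(n, alpha) {
    if (length(n) != 1L || !is.finite(n) || n < 3 || n != round(n))
        stop("'n' must be a single integer >= 3", call. = FALSE)
    if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
        stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
    invisible(NULL)
}

#' Extrema of the Phi coefficient given two OTU prevalences
#'
#' The Phi coefficient of two binary occurrence variables is constrained by
#' the marginal prevalences \eqn{P_A, P_B}: the joint prevalence \eqn{P_{11}}
#' can only range over \eqn{[\max(0, P_A+P_B-1), \min(P_A, P_B)]}, so Phi
#' cannot reach \eqn{\pm 1} unless the prevalences allow it.  The attainable
#' extrema are
#' \deqn{\min(\phi) = \max\left(-\sqrt{\frac{P_A P_B}{(1-P_A)(1-P_B)}},
#'   -\sqrt{\frac{(1-P_A)(1-P_B)}{P_A P_B}}\right)}
#' \deqn{\max(\phi) = \min\left(+\sqrt{\frac{P_A (1-P_B)}{P_B (1-P_A)}},
#'   +\sqrt{\frac{P_B (1-P_A)}{P_A (1-P_B)}}\right)}
#' The maximum equals 1 exactly when \eqn{P_A = P_B}; the minimum equals
#' \eqn{-1} exactly when \eqn{P_A + P_B = 1}.
#'
#' @param pA,pB numeric vectors of prevalences, strictly in (0, 1);
#'   recycled to common length.
#' @return a data.frame with columns \code{min} (in \eqn{[-1,0)}) and
#'   \code{max} (in \eqn{(0,1]}), one row per input pair.
#' @examples
#' phiExtrema(0.3, 0.6)
#' phiExtrema(c(0.5, 0.1), c(0.5, 0.1))
#' @export
phiExtrema <- function(pA, pB) {
    .checkPrevalence(pA, "pA"); .checkPrevalence(pB, "pB")
    lo <- pmax(-sqrt(pA * pB / ((1 - pA) * (1 - pB))),
               -sqrt((1 - pA) * (1 - pB) / (pA * pB)))
    hi <- pmin(sqrt(pA * (1 - pB) / (pB * (1 - pA))),
               sqrt(pB * (1 - pA) / (pA * (1 - pB))))
    data.frame(min = lo, max = hi)
}

#' Minimum attainable Pearson (and Spearman) correlation given prevalences
#'
#' For two non-negative abundance variables with prevalences \eqn{P_A, P_B}
#' such that \eqn{P_A + P_B < 1}, the sample Pearson correlation is bounded
#' below by \eqn{-\sqrt{P_A P_B / ((1-P_A)(1-P_B))} > -1}; the bound is
#' attained by constant positive abundances on disjoint supports.  The same
#' bound holds for the Spearman correlation (ranks preserve the
#' zero/non-zero pattern).  When \eqn{P_A + P_B \ge 1} the two supports
#' necessarily overlap and co-present samples can be arranged
#' anti-monotonically, so the correlation can approach \eqn{-1}; the bound
#' returned there is \eqn{-1}.  The maximum is not prevalence-constrained
#' (it is always 1, attained by proportional abundances on a common
#' support), which is why only the minimum matters for testability.
#'
#' @inheritParams phiExtrema
#' @return numeric vector of lower bounds in \eqn{[-1, 0)}.
#' @examples
#' pearsonMin(0.2, 0.2)   # -0.25
#' pearsonMin(0.5, 0.5)   # -1: complementary occurrence is possible
#' @export
pearsonMin <- function(pA, pB) {
    .checkPrevalence(pA, "pA"); .checkPrevalence(pB, "pB")
    ifelse(pA + pB < 1, -sqrt(pA * pB / ((1 - pA) * (1 - pB))), -1)
}

#' Critical value of the Phi coefficient under the chi-squared approximation
#'
#' Under independence, \eqn{N \phi^2} is approximately chi-squared with one
#' degree of freedom, so \eqn{|\phi|} exceeds
#' \eqn{\sqrt{\chi^2_{1,1-\alpha}/N}} with probability \eqn{\alpha}.  The
#' chi-squared test is two-sided in \eqn{\phi} (both signs are folded into
#' \eqn{\phi^2}), so no further alpha splitting is applied.
#'
#' @param n integer sample count, at least 3.
#' @param alpha significance level in (0, 1).
#' @return the critical absolute Phi value.
#' @examples
#' phiCritical(50)    # 0.2772
#' phiCritical(200)   # halves when n quadruples
#' @export
phiCritical <- function(n, alpha = 0.05) {
    .checkSettings(n, alpha)
    sqrt(stats::qchisq(1 - alpha, df = 1) / n)
}

#' Critical value of the Pearson/Spearman correlation under the Student test
#'
#' Under independence of two (normal) variables,
#' \eqn{t = r\sqrt{N-2}/\sqrt{1-r^2}} follows a Student distribution with
#' \eqn{N-2} degrees of freedom.  The two-sided critical correlation at
#' level \eqn{\alpha} is \eqn{t_{1-\alpha/2} / \sqrt{N - 2 + t_{1-\alpha/2}^2}}.
#' The same null distribution is conventionally used for the Spearman
#' coefficient, which drops the normality assumption.
#'
#' @inheritParams phiCritical
#' @return the critical absolute correlation.
#' @examples
#' rCritical(50)  # 0.2787
#' rCritical(12)  # 0.5760
#' @export
rCritical <- function(n, alpha = 0.05) {
    .checkSettings(n, alpha)
    tq <- stats::qt(1 - alpha / 2, df = n - 2)
    tq / sqrt(n - 2 + tq^2)
}

.category <- function(pos, neg) {
    out <- character(length(pos))
    out[pos & neg] <- "full"
    out[pos & !neg] <- "positive_only"
    out[!pos & neg] <- "negative_only"
    out[!pos & !neg] <- "none"
    out
}

.verdictFrame <- function(pos, neg) {
    data.frame(positive_testable = pos, negative_testable = neg,
               category = .category(pos, neg))
}

#' Classify testability of an OTU pair from occurrence data
#'
#' A direction is testable when the corresponding attainable extremum of the
#' Phi coefficient lies beyond the chi-squared critical value at the given
#' sample size: no observable 2x2 table can otherwise produce a significant
#' association in that direction, whatever the data.
#'
#' @inheritParams phiExtrema
#' @inheritParams phiCritical
#' @return a data.frame with logical columns \code{positive_testable},
#'   \code{negative_testable} and a \code{category} column taking values
#'   \code{"full"}, \code{"positive_only"}, \code{"negative_only"},
#'   \code{"none"}.
#' @examples
#' classifyOccurrence(0.1, 0.1, n = 50)   # positive_only
#' classifyOccurrence(0.5, 0.5, n = 50)   # full
#' @export
classifyOccurrence <- function(pA, pB, n, alpha = 0.05) {
    ext <- phiExtrema(pA, pB)
    crit <- phiCritical(n, alpha)
    .verdictFrame(ext$max > crit, ext$min < -crit)
}

#' Classify testability of an OTU pair from read-abundance data
#'
#' The maximum of the Pearson/Spearman correlation is not constrained by
#' prevalence, so positive associations are always testable.  Negative
#' associations are testable only when the prevalence-determined lower
#' bound (\code{\link{pearsonMin}}) lies below minus the Student critical
#' correlation.
#'
#' @inheritParams classifyOccurrence
#' @return as \code{\link{classifyOccurrence}}; the category is always
#'   \code{"full"} or \code{"positive_only"}.
#' @examples
#' classifyAbundance(0.2, 0.2, n = 50)  # positive_only: floor -0.25 too shallow
#' classifyAbundance(0.3, 0.3, n = 50)  # full
#' @export
classifyAbundance <- function(pA, pB, n, alpha = 0.05) {
    lo <- pearsonMin(pA, pB)
    crit <- rCritical(n, alpha)
    .verdictFrame(rep(TRUE, length(lo)), lo < -crit)
}

#' Classify testability of an OTU pair under Fisher's exact test
#'
#' With occupancy counts \eqn{a, b} out of \eqn{n} samples, the
#' co-occurrence count \eqn{K} follows the hypergeometric law under
#' independence and is confined to
#' \eqn{[\max(0, a+b-n), \min(a, b)]}.  The positive direction is testable
#' when even the largest possible \eqn{K} has one-sided upper tail
#' probability at most \eqn{\alpha}; the negative direction when the
#' smallest possible \eqn{K} has lower tail probability at most
#' \eqn{\alpha}.  Boundary ties (p exactly \eqn{\alpha}) count as testable.
#'
#' @param countA,countB integer occupancy counts, strictly between 0 and
#'   \code{n}; recycled to common length.
#' @inheritParams phiCritical
#' @return as \code{\link{classifyOccurrence}}.
#' @examples
#' fisherTestability(2, 2, n = 20)    # positive_only
#' fisherTestability(10, 10, n = 20)  # full
#' @export
fisherTestability <- function(countA, countB, n, alpha = 0.05) {
    .checkSettings(n, alpha)
    if (anyNA(countA) || anyNA(countB) ||
        any(countA != round(countA)) || any(countB != round(countB)))
        stop("occupancy counts must be integers", call. = FALSE)
    if (any(countA <= 0 | countA >= n | countB <= 0 | countB >= n))
        stop("occupancy counts must lie strictly between 0 and n", call. = FALSE)
    k <- cbind(countA + numeric(length(countB)), countB + numeric(length(countA)))
    a <- k[, 1L]; b <- k[, 2L]
    kMax <- pmin(a, b)
    kMin <- pmax(0, a + b - n)
    pUpper <- stats::dhyper(kMax, a, n - a, b)   # P(K >= kMax) = P(K = kMax)
    pLower <- stats::phyper(kMin, a, n - a, b)   # P(K <= kMin) = P(K = kMin)
    .verdictFrame(pUpper <= alpha, pLower <= alpha)
}
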