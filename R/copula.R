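#' Zero-inflated negative binomial and Poisson marginals
#'
#' Parameter constructors and distribution functions for the count
#' marginals used by the copula simulator.  The negative binomial
#' component is parameterized by its mean \eqn{\mu} and dispersion
#' \eqn{\theta} with variance \eqn{\mu + \mu^2/\theta} (so
#' \eqn{\theta = 0.5} is heavy overdispersion; note that some texts call
#' \eqn{1/\theta} the dispersion).  \code{pZero} is the probability of a
#' structural zero; the structural prevalence of the OTU is
#' \eqn{1 - p_0}.  Realized prevalence is slightly lower because the
#' count component can also produce (sampling) zeros.
#'
#' @param pZero structural-zero probability in [0, 1).
#' @param mean negative binomial mean \eqn{\mu} (default 1000, a highly
#'   abundant OTU).
#' @param dispersion negative binomial \eqn{\theta} (default 0.5).
#' @param lambda Poisson rate for the ZIP marginal.
#' @return a marginal-description list with a \code{type} field.
#' @examples
#' zinbParams(pZero = 0.2)
#' zipParams(pZero = 0.5, lambda = 10)
#' @name marginals
#' @rdname marginals
#' @export
zinbParams <- function(pZero, mean = 1000, dispersion = 0.5) {
    stopifnot(pZero >= 0, pZero < 1, mean > 0, dispersion > 0)
    list(type = "zinb", pZero = pZero, mean = mean, dispersion = dispersion)
}

#' @rdname marginals
#' @export
zipParams <- function(pZero, lambda) {
    stopifnot(pZero >= 0, pZero < 1, lambda > 0)
    list(type = "zip", pZero = pZero, lambda = lambda)
}

#' @param u probabilities in [0, 1].
#' @param x non-negative counts.
#' @param params a marginal description from \code{zinbParams} or
#'   \code{zipParams}.
#' @details \code{qMarginal} is the quantile function: the structural-zero
#'   mass absorbs the lower \code{pZero} tail of \code{u}, the remainder is
#'   mapped through the count-component quantile.  \code{pMarginal} is the
#'   CDF.  Together they satisfy
#'   \code{qMarginal(pMarginal(x)) <= x < qMarginal(pMarginal(x) + eps)}.
#' @rdname marginals
#' @export
qMarginal <- function(u, params) {
    p0 <- params$pZero
    q <- numeric(length(u))
    pos <- u > p0
    u2 <- (u[pos] - p0) / (1 - p0)
    q[pos] <- switch(params$type,
        zinb = stats::qnbinom(u2, size = params$dispersion, mu = params$mean),
        zip = stats::qpois(u2, lambda = params$lambda),
        stop("unknown marginal type"))
    q
}

#' @rdname marginals
#' @export
pMarginal <- function(x, params) {
    p0 <- params$pZero
    p0 + (1 - p0) * switch(params$type,
        zinb = stats::pnbinom(x, size = params$dispersion, mu = params$mean),
        zip = stats::ppois(x, lambda = params$lambda),
        stop("unknown marginal type"))
}

#' Correlation matrix with a target condition number from a signed adjacency
#'
#' Builds a precision-like matrix \eqn{\Theta = d I - w A} from the signed
#' adjacency \eqn{A} (so that, after inversion, correlations on edges carry
#' the sign of the edge), solves for the diagonal inflation \eqn{d} such
#' that the condition number (largest over smallest eigenvalue) of the
#' resulting correlation matrix equals \code{conditionTarget}, inverts, and
#' standardizes.  Larger \eqn{d} gives a better conditioned, weaker
#' correlation structure; the 1-D root find makes the condition-number
#' constraint the binding contract of the construction.
#'
#' @param adjacency symmetric integer matrix with entries -1/0/+1 and zero
#'   diagonal.
#' @param conditionTarget desired condition number of the output
#'   correlation matrix (default 100).
#' @param w edge-weight magnitude placed on the precision off-diagonals
#'   before inflation (default 1).
#' @return the correlation matrix, with attributes \code{conditionNumber}
#'   (achieved value) and \code{d} (diagonal inflation used).
#' @examples
#' a <- matrix(0L, 4, 4); a[1, 2] <- a[2, 1] <- 1L; a[3, 4] <- a[4, 3] <- -1L
#' c4 <- makeCorrelationMatrix(a, conditionTarget = 10)
#' attr(c4, "conditionNumber")
#' @export
makeCorrelationMatrix <- function(adjacency, conditionTarget = 100, w = 1) {
    p <- nrow(adjacency)
    stopifnot(ncol(adjacency) == p, all(adjacency %in% c(-1L, 0L, 1L)),
              all(diag(adjacency) == 0), isTRUE(all.equal(adjacency,
                                                          t(adjacency))))
    if (all(adjacency == 0)) {
        if (conditionTarget != 1)
            warning("empty adjacency: condition target forced to 1",
                    call. = FALSE)
        out <- diag(p)
        attr(out, "conditionNumber") <- 1
        attr(out, "d") <- 1
        return(out)
    }
    if (conditionTarget <= 1)
        stop("'conditionTarget' must exceed 1 for a non-empty adjacency",
             call. = FALSE)
    A <- -w * adjacency
    lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    dMin <- -min(lam) + 1e-8
    condAt <- function(d) {
        Theta <- A; diag(Theta) <- d
        Sigma <- chol2inv(chol(Theta))
        ev <- eigen(stats::cov2cor(Sigma), symmetric = TRUE,
                    only.values = TRUE)$values
        ev[1L] / ev[p]
    }
    lo <- dMin + 1e-6 * max(1, dMin)
    cLo <- condAt(lo)
    if (cLo < conditionTarget)
        stop(sprintf(paste0("condition target %.3g infeasible: maximum ",
                            "achievable is %.3g"), conditionTarget, cLo),
             call. = FALSE)
    hi <- lo + 1
    while (condAt(hi) > conditionTarget) hi <- hi * 2
    d <- stats::uniroot(function(x) log(condAt(x)) - log(conditionTarget),
                        lower = lo, upper = hi, tol = 1e-10)$root
    Theta <- A; diag(Theta) <- d
    out <- stats::cov2cor(chol2inv(chol(Theta)))
    attr(out, "conditionNumber") <- condAt(d)
    attr(out, "d") <- d
    out
}

#' Zero-inflated counts from a Gaussian copula
#'
#' Draws latent multivariate-normal samples with the given correlation,
#' maps each coordinate through the standard normal CDF, and inverts the
#' per-OTU zero-inflated quantile function, yielding counts whose
#' marginals are exactly the requested ZINB/ZIP laws while the dependence
#' structure is inherited from the latent correlation.
#'
#' @param correlation symmetric positive-definite correlation matrix
#'   (p x p).
#' @param nSamples number of samples to draw.
#' @param marginals list of length p of marginal descriptions
#'   (\code{\link{zinbParams}} / \code{\link{zipParams}}); a single
#'   description is recycled.
#' @param rngSeed integer seed.
#' @return an nSamples x p integer-valued count matrix.
#' @examples
#' cc <- diag(2); cc[1, 2] <- cc[2, 1] <- 0.7
#' m <- gaussianCopulaCounts(cc, 100, zinbParams(pZero = 0.3), rngSeed = 1)
#' @export
gaussianCopulaCounts <- function(correlation, nSamples, marginals, rngSeed) {
    p <- nrow(correlation)
    if (!is.null(marginals$type)) marginals <- rep(list(marginals), p)
    stopifnot(length(marginals) == p)
    z <- .withSeed(rngSeed,
                   matrix(stats::rnorm(nSamples * p), nSamples, p))
    z <- z %*% chol(correlation)
    u <- stats::pnorm(z)
    counts <- vapply(seq_len(p),
                     function(j) qMarginal(u[, j], marginals[[j]]),
                     numeric(nSamples))
    matrix(counts, nrow = nSamples, ncol = p)
}

#' Simulate a correlated pair of zero-inflated OTU count vectors
#'
#' Two-OTU Gaussian copula with the latent correlation set to the
#' requested level; levels \eqn{\pm 1} are clamped to \eqn{\pm 0.999}
#' since a singular 2x2 correlation matrix is infeasible, making them the
#' strongest representable (anti-)monotone coupling.
#'
#' @param level latent correlation level in [-1, 1]; the interesting
#'   settings are -1, 0 and +1.
#' @param pA,pB prevalences of the two OTUs (structural-zero probability
#'   \code{1 - p}).
#' @param n number of samples.
#' @param params marginal template (default ZINB, mean 1000, dispersion
#'   0.5); its \code{pZero} is overridden per OTU.
#' @param rngSeed integer seed.
#' @return an n x 2 count matrix.
#' @examples
#' xy <- simulatePair(-1, 0.9, 0.9, n = 50, rngSeed = 3)
#' cor(xy[, 1], xy[, 2], method = "spearman")
#' @export
simulatePair <- function(level, pA, pB, n, params = zinbParams(0),
                         rngSeed) {
    stopifnot(abs(level) <= 1)
    rho <- sign(level) * min(abs(level), 0.999)
    cc <- matrix(c(1, rho, rho, 1), 2, 2)
    mA <- params; mA$pZero <- 1 - pA
    mB <- params; mB$pZero <- 1 - pB
    gaussianCopulaCounts(cc, n, list(mA, mB), rngSeed)
}

#' Simulate a whole community with known signed association structure
#'
#' Places \code{nEdges} signed edges uniformly at random among the OTU
#' pairs, builds the target-condition-number correlation matrix
#' (\code{\link{makeCorrelationMatrix}}), assigns each OTU a structural
#' prevalence (constant, or drawn from a truncated power law), and draws
#' zero-inflated counts through the Gaussian copula
#' (\code{\link{gaussianCopulaCounts}}).
#'
#' @param nOtus,nSamples community dimensions.
#' @param nEdges number of true associations (at most
#'   \code{choose(nOtus, 2)}).
#' @param positiveFraction fraction of edges that are positive (default
#'   0.5).
#' @param conditionTarget condition number of the generating correlation
#'   matrix (default 100).
#' @param prevalence either a single number (all OTUs share that
#'   structural prevalence) or a list
#'   \code{list(k = , pMin = )} describing a truncated power law to draw
#'   per-OTU prevalences from.
#' @param params marginal template, see \code{\link{simulatePair}}.
#' @param rngSeed integer seed; edge placement, prevalence draws and
#'   counts all derive from it.
#' @return a \code{\linkS4class{SimulatedCommunity}}.
#' @examples
#' sim <- simulateCommunity(20, 50, nEdges = 10, prevalence = 0.8,
#'                          conditionTarget = 10, rngSeed = 1)
#' sim
#' @export
simulateCommunity <- function(nOtus, nSamples, nEdges,
                              positiveFraction = 0.5, conditionTarget = 100,
                              prevalence = 0.8, params = zinbParams(0),
                              rngSeed) {
    nPairs <- choose(nOtus, 2L)
    stopifnot(nEdges <= nPairs, nEdges >= 0)
    state <- .withSeed(rngSeed, {
        sel <- sample.int(nPairs, nEdges)
        nPos <- round(nEdges * positiveFraction)
        sgn <- sample(c(rep(1L, nPos), rep(-1L, nEdges - nPos)))
        prev <- if (is.numeric(prevalence) && length(prevalence) %in%
                    c(1L, nOtus)) {
            rep_len(prevalence, nOtus)
        } else {
            pMin <- prevalence$pMin %||% (5 / nSamples)
            .powerlawQuantile(stats::runif(nOtus), prevalence$k, pMin)
        }
        list(sel = sel, sgn = sgn, prev = prev)
    })
    idx <- which(upper.tri(diag(nOtus)), arr.ind = TRUE)
    truth <- matrix(0L, nOtus, nOtus)
    truth[idx[state$sel, , drop = FALSE]] <- state$sgn
    truth <- truth + t(truth)
    correlation <- makeCorrelationMatrix(truth, conditionTarget)
    marginals <- lapply(state$prev, function(pv) {
        m <- params; m$pZero <- 1 - pv; m
    })
    counts <- gaussianCopulaCounts(correlation, nSamples, marginals,
                                   rngSeed = rngSeed + 1L)
    otuIds <- sprintf("OTU%03d", seq_len(nOtus))
    dimnames(truth) <- dimnames(correlation) <- list(otuIds, otuIds)
    se <- SummarizedExperiment(
        assays = list(counts = t(counts)),
        rowData = DataFrame(targetPrevalence = state$prev,
                            mean = vapply(marginals, function(m)
                                m$mean %||% m$lambda, 0),
                            row.names = otuIds),
        colData = DataFrame(row.names = sprintf("S%03d", seq_len(nSamples))),
        metadata = list(truth = truth, correlation = correlation,
                        conditionNumber = attr(correlation,
                                               "conditionNumber"),
                        rngSeed = rngSeed,
                        spec = list(nOtus = nOtus, nSamples = nSamples,
                                    nEdges = nEdges,
                                    positiveFraction = positiveFraction,
                                    conditionTarget = conditionTarget,
                                    prevalence = prevalence)))
    as(se, "SimulatedCommunity")
}
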