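#' Prevalence response surfaces of association measures
#'
#' For each unordered pair of prevalences on the grid, simulates
#' \code{reps} count-vector pairs with the requested latent correlation
#' level through the ZINB Gaussian copula (\code{\link{simulatePair}}),
#' computes the requested association measures on each, and records the
#' median.  The same simulated data are reused across measures, so
#' surfaces of different measures are directly comparable cell by cell.
#'
#' @param measures character vector of measures
#'   (see \code{\link{associationMeasure}}).
#' @param level latent correlation level (-1, 0 or +1 in the canonical
#'   experiment).
#' @param prevalenceGrid prevalence values (default 0.05 to 0.95 in 0.05
#'   steps).
#' @param n samples per simulated pair (default 50).
#' @param reps simulations per cell (default 100).
#' @param params marginal template (default ZINB, mean 1000,
#'   dispersion 0.5).
#' @param rngSeed integer seed.
#' @param maxPrevalenceSum if finite, only grid cells with
#'   \eqn{p_A + p_B \le} this value are computed (the rest are NA); used
#'   to restrict to the low-prevalence region.
#' @return a named list of symmetric matrices (one per measure) of median
#'   measure values, with the grid as dimnames.
#' @examples
#' rs <- responseSurface("spearman", level = -1,
#'                       prevalenceGrid = c(0.3, 0.6, 0.9),
#'                       reps = 10, rngSeed = 1)
#' @export
responseSurface <- function(measures, level,
                            prevalenceGrid = seq(0.05, 0.95, by = 0.05),
                            n = 50, reps = 100, params = zinbParams(0),
                            rngSeed, maxPrevalenceSum = Inf) {
    g <- length(prevalenceGrid)
    out <- lapply(measures, function(m)
        matrix(NA_real_, g, g, dimnames = list(prevalenceGrid,
                                               prevalenceGrid)))
    names(out) <- measures
    counter <- 0L
    for (i in seq_len(g)) for (j in i:g) {
        pA <- prevalenceGrid[i]; pB <- prevalenceGrid[j]
        counter <- counter + 1L
        if (pA + pB > maxPrevalenceSum) next
        vals <- matrix(NA_real_, reps, length(measures))
        for (r in seq_len(reps)) {
            xy <- simulatePair(level, pA, pB, n, params,
                               rngSeed = rngSeed + 1013L * counter + r)
            for (mIdx in seq_along(measures))
                vals[r, mIdx] <- suppressWarnings(
                    associationMeasure(xy[, 1L], xy[, 2L],
                                       measures[mIdx])$value)
        }
        med <- apply(vals, 2L, stats::median, na.rm = TRUE)
        for (mIdx in seq_along(measures)) {
            out[[mIdx]][i, j] <- med[mIdx]
            out[[mIdx]][j, i] <- med[mIdx]
        }
    }
    out
}

#' Coupling between the Phi and Pearson coefficients at low prevalence
#'
#' For each combination of structural-zero probability \eqn{p_0} and
#' Poisson rate \eqn{\lambda}, generates \code{reps} independent pairs of
#' ZIP-distributed OTU vectors, computes the Phi coefficient and the
#' Pearson correlation on each pair, and returns the correlation between
#' the two statistics across repeats.  A high coupling means occurrence
#' and abundance data carry essentially the same association information
#' - which is what happens as prevalence decreases.  Repeats where either
#' statistic is undefined (constant vector) are excluded and counted.
#'
#' @param pZeroGrid structural-zero probabilities to scan.
#' @param lambdaGrid Poisson rates to scan.
#' @param n samples per repeat (default 100).
#' @param reps repeats per cell (default 1e4; raise for publication-grade
#'   smoothness).
#' @param rngSeed integer seed.
#' @return data.frame with columns \code{pZero}, \code{lambda},
#'   \code{coupling} (correlation of the two coefficients),
#'   \code{nUsed}, \code{nExcluded}.
#' @examples
#' phiPearsonCoupling(c(0.5, 0.9), 5, reps = 500, rngSeed = 2)
#' @export
phiPearsonCoupling <- function(pZeroGrid, lambdaGrid, n = 100, reps = 1e4,
                               rngSeed) {
    grid <- expand.grid(pZero = pZeroGrid, lambda = lambdaGrid)
    res <- .withSeed(rngSeed, {
        lapply(seq_len(nrow(grid)), function(gi) {
            p0 <- grid$pZero[gi]; lam <- grid$lambda[gi]
            x <- matrix(stats::rpois(n * reps, lam) *
                        (stats::runif(n * reps) >= p0), n, reps)
            y <- matrix(stats::rpois(n * reps, lam) *
                        (stats::runif(n * reps) >= p0), n, reps)
            ax <- x > 0; ay <- y > 0
            pa <- colMeans(ax); pb <- colMeans(ay)
            p11 <- colMeans(ax & ay)
            phi <- (p11 - pa * pb) / sqrt(pa * (1 - pa) * pb * (1 - pb))
            mx <- colMeans(x); my <- colMeans(y)
            sx <- sqrt(colMeans(x^2) - mx^2)
            sy <- sqrt(colMeans(y^2) - my^2)
            r <- (colMeans(x * y) - mx * my) / (sx * sy)
            ok <- is.finite(phi) & is.finite(r)
            data.frame(pZero = p0, lambda = lam,
                       coupling = if (sum(ok) >= 3L)
                           stats::cor(phi[ok], r[ok]) else NA_real_,
                       nUsed = sum(ok), nExcluded = sum(!ok))
        })
    })
    do.call(rbind, res)
}
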