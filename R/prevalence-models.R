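.withSeed <- function(seed, expr) {
    if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
        stop("'rngSeed' must be a single integer", call. = FALSE)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(as.integer(seed))
    expr
}

.classifyPrevPairs <- function(pA, pB, n, alpha, mode) {
    switch(mode,
        occurrence_phi = classifyOccurrence(pA, pB, n, alpha),
        occurrence_fisher = fisherTestability(pmin(pmax(round(pA * n), 1L),
                                                   n - 1L),
                                              pmin(pmax(round(pB * n), 1L),
                                                   n - 1L), n, alpha),
        abundance = classifyAbundance(pA, pB, n, alpha))
}

.proportionsFromVerdicts <- function(v, nPairs = nrow(v)) {
    cat4 <- factor(v$category, levels = names(.CATEGORY_CODES))
    tab <- table(cat4) / nrow(v)
    out <- as.data.frame(as.list(as.numeric(tab)))
    names(out) <- names(.CATEGORY_CODES)
    out$se <- sqrt(out$full * (1 - out$full) / nPairs)
    out
}

#' Testability proportions under a uniform prevalence distribution
#'
#' Enumerates every integer occupancy pair \eqn{(a, b)} with
#' \eqn{1 \le a, b \le n - 1} (the prevalence values actually observable at
#' sample size \eqn{n}, excluding the degenerate 0 and \eqn{n}), classifies
#' each pair, and returns the exact category frequencies.  This is the
#' deterministic, enumeration-based counterpart of the Monte-Carlo
#' \code{\link{powerlawProportions}}.
#'
#' @inheritParams phiCritical
#' @param mode classifier mode, see \code{\link{testabilityMask}}.
#' @return one-row data.frame with columns \code{full},
#'   \code{positive_only}, \code{negative_only}, \code{none} (summing to
#'   1), \code{se} (0: exact), \code{n}, \code{mode}.
#' @examples
#' uniformProportions(300, mode = "occurrence_phi")
#' @export
uniformProportions <- function(n, alpha = 0.05,
                               mode = c("occurrence_phi",
                                        "occurrence_fisher", "abundance")) {
    mode <- match.arg(mode)
    .checkSettings(n, alpha)
    a <- rep(seq_len(n - 1L), times = n - 1L)
    b <- rep(seq_len(n - 1L), each = n - 1L)
    v <- .classifyPrevPairs(a / n, b / n, n, alpha, mode)
    out <- .proportionsFromVerdicts(v)
    out$se <- 0
    out$n <- n
    out$mode <- mode
    out
}

#' Sample prevalences from a truncated power law
#'
#' Draws prevalences with density proportional to \eqn{p^k} on
#' \eqn{[p_{\min}, 1]} by inversion of the analytic CDF.  Exponents around
#' \eqn{k \in [-2, -1]} reproduce the rare-species-dominated prevalence
#' distributions of real 16S communities; \eqn{k = 0} degenerates to the
#' uniform distribution on \eqn{[p_{\min}, 1]}.
#'
#' @param k power-law exponent.
#' @param pMin lower truncation, strictly in (0, 1).
#' @param size number of draws.
#' @param rngSeed integer seed (mandatory; the global RNG state is left
#'   untouched).
#' @return numeric vector of prevalences in \eqn{[p_{\min}, 1]}.
#' @examples
#' p <- powerlawSample(-1.5, pMin = 5 / 300, size = 1000, rngSeed = 1)
#' @export
powerlawSample <- function(k, pMin, size, rngSeed) {
    if (pMin <= 0 || pMin >= 1) stop("'pMin' must be in (0, 1)", call. = FALSE)
    u <- .withSeed(rngSeed, stats::runif(size))
    .powerlawQuantile(u, k, pMin)
}

.powerlawQuantile <- function(u, k, pMin) {
    if (abs(k + 1) < 1e-9) {
        pMin^(1 - u)
    } else {
        a <- k + 1
        (u * (1 - pMin^a) + pMin^a)^(1 / a)
    }
}

.powerlawCdf <- function(p, k, pMin) {
    if (abs(k + 1) < 1e-9) log(p / pMin) / log(1 / pMin)
    else (p^(k + 1) - pMin^(k + 1)) / (1 - pMin^(k + 1))
}

#' Maximum-likelihood fit of the truncated power-law exponent
#'
#' Maximizes the truncated power-law log-likelihood
#' \eqn{\ell(k) = k \sum_i \log p_i - m \log Z(k)} with
#' \eqn{Z(k) = (1 - p_{\min}^{k+1}) / (k + 1)} over the \eqn{m}
#' observations at or above \code{pMin}, by 1-D numerical optimization.
#'
#' @param prevalences numeric vector of observed prevalences in (0, 1].
#' @param pMin lower truncation; observations below it are dropped.
#' @param interval search interval for the exponent.
#' @return a list with elements \code{k} (the MLE), \code{logLik},
#'   \code{pMin} and \code{nUsed}.
#' @examples
#' p <- powerlawSample(-1.5, 0.02, 2000, rngSeed = 7)
#' powerlawFit(p, pMin = 0.02)$k
#' @export
powerlawFit <- function(prevalences, pMin = min(prevalences),
                        interval = c(-8, 8)) {
    x <- prevalences[prevalences >= pMin & prevalences <= 1]
    if (length(x) < 10L)
        stop("fewer than 10 observations at or above pMin", call. = FALSE)
    if (stats::sd(x) == 0)
        stop("constant prevalences: power-law exponent is unidentifiable",
             call. = FALSE)
    if (pMin <= 0 || pMin >= 1) stop("'pMin' must be in (0, 1)", call. = FALSE)
    slog <- sum(log(x)); m <- length(x)
    negll <- function(k) {
        lz <- if (abs(k + 1) < 1e-9) log(log(1 / pMin))
              else log((1 - pMin^(k + 1)) / (k + 1))
        -(k * slog - m * lz)
    }
    opt <- stats::optimize(negll, interval = interval)
    if (min(abs(opt$minimum - interval)) < 1e-3)
        warning("exponent estimate at search boundary", call. = FALSE)
    list(k = opt$minimum, logLik = -opt$objective, pMin = pMin, nUsed = m)
}

#' Monte-Carlo testability proportions under a power-law prevalence model
#'
#' Draws \code{nPairs} independent prevalence pairs from the truncated
#' power law, classifies each with the requested rule, and returns category
#' frequencies with binomial standard errors.
#'
#' @inheritParams powerlawSample
#' @inheritParams uniformProportions
#' @param nPairs number of Monte-Carlo pairs (default 1e5).
#' @param pMin lower truncation; defaults to \code{1 / n}, the smallest
#'   prevalence observable at sample size \code{n} (an OTU present in a
#'   single sample).
#' @return one-row data.frame as \code{\link{uniformProportions}}, with
#'   binomial \code{se} and the model parameters appended.
#' @examples
#' powerlawProportions(-1, n = 100, mode = "abundance", nPairs = 1e4,
#'                     rngSeed = 1)
#' @export
powerlawProportions <- function(k, n, alpha = 0.05,
                                mode = c("occurrence_phi",
                                         "occurrence_fisher", "abundance"),
                                pMin = 1 / n, nPairs = 1e5, rngSeed) {
    mode <- match.arg(mode)
    .checkSettings(n, alpha)
    pp <- powerlawSample(k, pMin, 2L * nPairs, rngSeed)
    pA <- pmin(pp[seq_len(nPairs)], 1 - 1e-12)
    pB <- pmin(pp[nPairs + seq_len(nPairs)], 1 - 1e-12)
    v <- .classifyPrevPairs(pA, pB, n, alpha, mode)
    out <- .proportionsFromVerdicts(v, nPairs)
    out$n <- n; out$mode <- mode; out$k <- k; out$pMin <- pMin
    out
}

#' Testability-proportion curves over sample size
#'
#' Tabulates testability category proportions for a series of sample
#' sizes, under either the exact uniform-grid enumeration or the
#' power-law Monte-Carlo model, in tidy long-by-n format.
#'
#' @param nValues integer vector of sample sizes.
#' @param distribution \code{"uniform"} or \code{"powerlaw"}.
#' @inheritParams powerlawProportions
#' @param pMin lower truncation for the power law; \code{NULL} (default)
#'   uses \code{1 / n} per sample size.
#' @param rngSeed seed, required when \code{distribution = "powerlaw"}.
#' @return data.frame with one row per sample size and the same columns as
#'   \code{\link{uniformProportions}} / \code{\link{powerlawProportions}}.
#' @examples
#' proportionCurve(c(50, 100, 300), "uniform", mode = "occurrence_phi")
#' @export
proportionCurve <- function(nValues, distribution = c("uniform", "powerlaw"),
                            mode = c("occurrence_phi", "occurrence_fisher",
                                     "abundance"),
                            k = -1.5, alpha = 0.05, pMin = NULL,
                            nPairs = 1e5, rngSeed = NULL) {
    distribution <- match.arg(distribution)
    mode <- match.arg(mode)
    rows <- lapply(seq_along(nValues), function(ii) {
        n <- nValues[ii]
        if (distribution == "uniform") {
            uniformProportions(n, alpha, mode)
        } else {
            if (is.null(rngSeed))
                stop("'rngSeed' is required for the power-law model",
                     call. = FALSE)
            powerlawProportions(k, n, alpha, mode,
                                pMin = if (is.null(pMin)) 1 / n else pMin,
                                nPairs = nPairs, rngSeed = rngSeed + ii)
        }
    })
    out <- do.call(rbind, lapply(rows, function(r) {
        r[setdiff(c("k", "pMin"), names(r))] <- NA
        r[c("n", "mode", "full", "positive_only", "negative_only", "none",
            "se", "k", "pMin")]
    }))
    out$distribution <- distribution
    rownames(out) <- NULL
    out
}
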