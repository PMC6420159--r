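test_that("zero-inflated quantile functions invert their CDFs", {
    grid <- list(zinbParams(0.3), zinbParams(0.7, mean = 50,
                                             dispersion = 2),
                 zinbParams(0, mean = 1000, dispersion = 0.5),
                 zipParams(0.5, 8), zipParams(0.05, 100))
    for (par in grid) {
        # q(u) is the smallest count whose CDF reaches u: F(q(u)) >= u
        # and, for q(u) > 0, F(q(u) - 1) < u
        u <- c(0.01, 0.2, 0.5, par$pZero + 1e-6, 0.9, 0.999)
        u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
        q <- qMarginal(u, par)
        expect_true(all(pMarginal(q, par) >= u - 1e-9))
        pos <- q > 0
        if (any(pos))
            expect_true(all(pMarginal(q[pos] - 1, par) < u[pos] + 1e-9))
    }
    # structural zeros absorb the lower tail exactly
    expect_equal(qMarginal(c(0, 0.29, 0.3), zinbParams(0.3)), c(0, 0, 0))
})

test_that("copula marginals recover prevalence and mean", {
    n <- 5000
    m <- gaussianCopulaCounts(diag(2), n, zinbParams(0.3), rngSeed = 5)
    # realized prevalence = (1 - p0) * (1 - P(NB = 0))
    pNb0 <- (0.5 / 1000.5)^0.5
    target <- 0.7 * (1 - pNb0)
    se <- sqrt(target * (1 - target) / n)
    for (j in 1:2)
        expect_lt(abs(mean(m[, j] > 0) - target), 3 * se)
    # E[count] = (1 - p0) * mu; Var >= mu + mu^2/theta scaled: use a wide
    # tolerance driven by the simulation SE of the mean
    seMean <- sd(m[, 1]) / sqrt(n)
    expect_lt(abs(mean(m[, 1]) - 0.7 * 1000), 4 * seMean)
})

test_that("identity correlation yields independent columns", {
    m <- gaussianCopulaCounts(diag(6), 400, zinbParams(0.2), rngSeed = 8)
    cc <- cor(m)
    expect_lt(mean(abs(cc[upper.tri(cc)])), 3 / sqrt(400))
})

test_that("correlation construction hits the condition target and edge
           signs", {
    set.seed(12)
    for (r in 1:20) {
        p <- sample(15:40, 1)
        nE <- sample(5:15, 1)
        a <- matrix(0L, p, p)
        sel <- sample(which(upper.tri(a)), nE)
        a[sel] <- sample(c(-1L, 1L), nE, replace = TRUE)
        a <- a + t(a)
        target <- sample(c(10, 50, 100), 1)
        cm <- makeCorrelationMatrix(a, target)
        expect_equal(attr(cm, "conditionNumber"), target,
                     tolerance = 0.01)
        ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
        expect_gt(min(ev), 0)
        expect_true(all(sign(cm[sel]) == a[sel]))
    }
    expect_warning(ci <- makeCorrelationMatrix(matrix(0L, 4, 4), 100),
                   "forced to 1")
    expect_identical(ci[1:4, 1:4], diag(4))
})

test_that("simulated pairs respond to the latent correlation level", {
    sp0 <- replicate(100, {
        xy <- simulatePair(0, 0.8, 0.8, 50,
                           rngSeed = sample.int(1e6, 1))
        suppressWarnings(cor(xy[, 1], xy[, 2], method = "spearman"))
    })
    expect_lt(abs(median(sp0, na.rm = TRUE)), 0.15)

    spP <- vapply(1:100, function(r) {
        xy <- simulatePair(1, 0.9, 0.9, 50, rngSeed = 4000 + r)
        cor(xy[, 1], xy[, 2], method = "spearman")
    }, 0)
    expect_gt(median(spP), 0.8)

    # Eq-6 floor: at low prevalence even a maximal negative latent
    # coupling cannot push Pearson much below the prevalence bound
    peN <- vapply(1:100, function(r) {
        xy <- simulatePair(-1, 0.2, 0.2, 50, rngSeed = 5000 + r)
        suppressWarnings(cor(xy[, 1], xy[, 2]))
    }, 0)
    expect_gte(median(peN, na.rm = TRUE), pearsonMin(0.2, 0.2))

    # monotonicity in the latent correlation
    med <- vapply(c(0.5, 0.9), function(lev) {
        median(vapply(1:100, function(r) {
            xy <- simulatePair(lev, 0.8, 0.8, 50, rngSeed = 6000 + r)
            cor(xy[, 1], xy[, 2], method = "spearman")
        }, 0))
    }, 0)
    expect_gt(med[2], med[1])
})

test_that("community simulation matches its specification", {
    sim <- simulateCommunity(100, 50, 100, prevalence = 0.8,
                             rngSeed = 17)
    expect_s4_class(sim, "SimulatedCommunity")
    expect_identical(dim(sim), c(100L, 50L))
    tr <- truthAdjacency(sim)
    up <- tr[upper.tri(tr)]
    expect_identical(sum(up != 0), 100L)
    expect_identical(sum(up == 1L), 50L)
    expect_equal(S4Vectors::metadata(sim)$conditionNumber, 100,
                 tolerance = 0.01)

    sim6 <- simulateCommunity(60, 300, 40,
                              prevalence = list(k = -1.5, pMin = 5 / 300),
                              rngSeed = 18)
    expect_true(all(targetPrevalence(sim6) >= 5 / 300))

    # bit-identical reproduction under the same seed
    simA <- simulateCommunity(30, 40, 20, prevalence = 0.7, rngSeed = 9)
    simB <- simulateCommunity(30, 40, 20, prevalence = 0.7, rngSeed = 9)
    expect_identical(SummarizedExperiment::assay(simA),
                     SummarizedExperiment::assay(simB))
    expect_identical(truthAdjacency(simA), truthAdjacency(simB))
})
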