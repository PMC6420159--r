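test_that("clr transform centers every sample", {
    m <- matrix(rpois(60, 10), nrow = 6)
    z <- clrTransform(m)
    expect_equal(rowSums(z), rep(0, 6), tolerance = 1e-9)
    # constant-composition sample maps to zero
    expect_equal(as.numeric(clrTransform(matrix(7, 1, 5))), rep(0, 5))
    # compositional invariance for positive counts as pseudocount -> 0
    mp <- matrix(rpois(60, 50) + 1, nrow = 6)
    z1 <- clrTransform(mp, pseudocount = 1e-9)
    z2 <- clrTransform(mp * 10, pseudocount = 1e-9)
    expect_equal(z1, z2, tolerance = 1e-6)
})

test_that("graphical lasso approaches the inverse correlation as the
           penalty vanishes", {
    set.seed(31)
    S0 <- diag(5)
    S0[1, 2] <- S0[2, 1] <- 0.5; S0[3, 4] <- S0[4, 3] <- -0.4
    x <- MASS::mvrnorm(4000, rep(0, 5), S0)
    fit <- graphicalLassoMasked(x, penalty = 1e-4)
    expect_lt(norm(fit$precision - solve(cor(x)), "F"), 0.05)
    expect_true(fit$converged)
    # strong penalty shrinks all off-diagonals to zero
    fitD <- graphicalLassoMasked(x, penalty = 5)
    off <- fitD$precision[upper.tri(fitD$precision)]
    expect_true(all(off == 0))
})

test_that("masked pairs are forced to zero even when truly associated", {
    set.seed(32)
    S5 <- diag(5); S5[1, 2] <- S5[2, 1] <- 0.8
    x <- MASS::mvrnorm(300, rep(0, 5), S5)
    mask <- matrix(FALSE, 5, 5); mask[1, 2] <- mask[2, 1] <- TRUE
    fit <- graphicalLassoMasked(x, penalty = 0.05, mask = mask)
    expect_identical(fit$precision[1, 2], 0)
    fitU <- graphicalLassoMasked(x, penalty = 0.05)
    expect_gt(abs(fitU$precision[1, 2]), 0.5)
})

test_that("prevalence filter removes the matched number of pairs", {
    kept <- prevalenceFilter(c(0.1, 0.9, 0.2, 0.8), 0)
    expect_identical(as.integer(kept), 1:4)
    p <- 12
    prev <- seq(0.05, 0.95, length.out = p)
    for (target in c(1, 11, 30, 50)) {
        kept <- prevalenceFilter(prev, target)
        m <- p - length(kept)
        expect_identical(attr(kept, "nFilteredPairs"),
                         choose(p, 2) - choose(p - m, 2))
        expect_gte(attr(kept, "nFilteredPairs"), target)
        # minimality: one fewer removal would miss the target
        if (m > 0)
            expect_lt(choose(p, 2) - choose(p - m + 1, 2), target)
    }
    # deterministic tie-break by index
    expect_identical(as.integer(prevalenceFilter(c(0.2, 0.2, 0.9), 2)),
                     c(2L, 3L))
})

test_that("network inference is deterministic and keeps its books", {
    sim <- simulateCommunity(20, 120, 12, prevalence = 0.5,
                             conditionTarget = 20, rngSeed = 51)
    sc1 <- inferNetwork(sim, filterMode = "testability", repetitions = 8,
                        nPenalties = 8, rngSeed = 52)
    sc2 <- inferNetwork(sim, filterMode = "testability", repetitions = 8,
                        nPenalties = 8, rngSeed = 52)
    expect_identical(edgeTable(sc1), edgeTable(sc2))

    prev <- prevalenceVector(sim)
    tm <- suppressWarnings(testabilityMask(prev, n = 120,
                                           mode = "abundance"))
    pp <- problematicPairs(tm)
    expect_identical(sum(edgeTable(sc1)$masked),
                     sum(pp[upper.tri(pp)], na.rm = TRUE))
    expect_true(all(edgeTable(sc1)$score[edgeTable(sc1)$masked] == 0))
    expect_error(inferNetwork(sim, penaltyPath = numeric(0), rngSeed = 1),
                 "empty penalty path")
})

test_that("strong edges are recovered on an easy benchmark", {
    rec <- vapply(1:5, function(s) {
        sim <- simulateCommunity(20, 200, 10, prevalence = 0.95,
                                 conditionTarget = 10, rngSeed = 300 + s)
        sc <- inferNetwork(sim, repetitions = 15, nPenalties = 12,
                           rngSeed = 400 + s)
        pr <- edgeTable(sc)
        tv <- abs(truthAdjacency(sim)[cbind(pr$i, pr$j)])
        sum(tv[order(abs(pr$score), decreasing = TRUE)[1:10]])
    }, 0)
    expect_gte(median(rec), 8)
})

test_that("masking leaves null-pair scores essentially unchanged", {
    diffs <- vapply(1:5, function(s) {
        sim <- simulateCommunity(25, 150, 15,
                                 prevalence = list(k = -1.5, pMin = 0.05),
                                 conditionTarget = 50, rngSeed = 600 + s)
        scN <- inferNetwork(sim, filterMode = "none", repetitions = 8,
                            nPenalties = 8, rngSeed = 700 + s)
        scT <- inferNetwork(sim, filterMode = "testability",
                            repetitions = 8, nPenalties = 8,
                            rngSeed = 700 + s)
        prN <- edgeTable(scN); prT <- edgeTable(scT)
        tv <- truthAdjacency(sim)[cbind(prN$i, prN$j)]
        nullUnmasked <- tv == 0 & !prT$masked
        median(abs(prT$score[nullUnmasked])) -
            median(abs(prN$score[nullUnmasked]))
    }, 0)
    # masking removes competitors, which can shift a little covariance
    # onto surviving null pairs; the median perturbation stays far below
    # the score scale of a real edge
    expect_lte(median(diffs), 0.03)
})
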