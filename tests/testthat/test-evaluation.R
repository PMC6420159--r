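test_that("signed AUC matches brute-force concordance and pROC", {
    set.seed(61)
    p <- 10
    truth <- matrix(0L, p, p)
    sel <- sample(which(upper.tri(truth)), 8)
    truth[sel] <- sample(c(1L, -1L), 8, replace = TRUE)
    truth <- truth + t(truth)
    scoreMat <- matrix(0, p, p)
    scoreMat[upper.tri(scoreMat)] <- round(rnorm(choose(p, 2)), 1)  # ties
    es <- makeEdgeScores(scoreMat)
    pr <- edgeTable(es)
    tv <- truth[cbind(pr$i, pr$j)]
    for (sg in c("positive", "negative")) {
        ev <- signedAuc(es, truth, sg)
        lab <- if (sg == "positive") tv == 1L else tv == -1L
        rk <- if (sg == "positive") pr$score else -pr$score
        expect_equal(ev$auc, bruteForceAuc(rk, lab))
        expect_equal(ev$auprc, bruteForceAveragePrecision(rk, lab))
        if (requireNamespace("pROC", quietly = TRUE))
            expect_equal(ev$auc,
                         as.numeric(pROC::auc(pROC::roc(lab, rk,
                             quiet = TRUE, direction = "<"))))
    }
})

test_that("perfect and random scorings bracket the AUC scale", {
    p <- 12
    truth <- matrix(0L, p, p)
    truth[1, 2] <- truth[2, 1] <- 1L
    truth[3, 4] <- truth[4, 3] <- -1L
    truth[5, 6] <- truth[6, 5] <- 1L
    es <- makeEdgeScores(truth * 1.0)
    expect_equal(signedAuc(es, truth, "positive")$auc, 1)
    expect_equal(signedAuc(es, truth, "negative")$auc, 1)

    set.seed(62)
    aucs <- replicate(100, {
        sm <- matrix(0, p, p)
        sm[upper.tri(sm)] <- rnorm(choose(p, 2))
        signedAuc(makeEdgeScores(sm), truth, "positive")$auc
    })
    expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(100))
})

test_that("masked pairs leave the evaluation denominator", {
    p <- 8
    truth <- matrix(0L, p, p)
    truth[1, 2] <- truth[2, 1] <- 1L
    truth[3, 4] <- truth[4, 3] <- 1L
    masked <- matrix(FALSE, p, p)
    masked[3, 4] <- masked[4, 3] <- TRUE
    sm <- matrix(0, p, p); sm[1, 2] <- 0.9
    ev <- signedAuc(makeEdgeScores(sm, masked), truth, "positive")
    expect_equal(ev$nCandidates, choose(p, 2L) - 1L)
    expect_equal(ev$nTrueEdges, 1L)              # the masked edge is gone
    expect_equal(ev$auc, 1)
    # no surviving true negatives -> undefined, flagged
    expect_warning(evN <- signedAuc(makeEdgeScores(sm, masked), truth,
                                    "negative"), "undefined")
    expect_true(is.na(evN$auc))
})

test_that("prevalence sweep benchmark shows the low-prevalence collapse", {
    tab <- prevalenceSweepBenchmark(prevalenceLevels = c(0.15, 0.95),
                                    nSims = 3, nOtus = 40, nSamples = 50,
                                    nEdges = 40, conditionTarget = 50,
                                    repetitions = 8, nPenalties = 8,
                                    rngSeed = 81)
    expect_equal(nrow(tab), 2 * 3 * 2)
    med <- aggregate(auc ~ prevalence + sign, tab, median)
    negLo <- med$auc[med$sign == "negative" & med$prevalence == 0.15]
    negHi <- med$auc[med$sign == "negative" & med$prevalence == 0.95]
    posLo <- med$auc[med$sign == "positive" & med$prevalence == 0.15]
    expect_gt(negHi, negLo)          # negatives recover with prevalence
    expect_gte(posLo, negLo)         # positives easier when rare
    expect_true(all(tab$realizedPrevalence[tab$prevalence == 0.15] < 0.3))
})

test_that("filtering benchmark orders testability above no filtering", {
    tab <- filteringBenchmark(scale = 0.2, nSims = 3,
                              modes = c("none", "testability",
                                        "prevalence"),
                              repetitions = 10, nPenalties = 10,
                              rngSeed = 91)
    expect_equal(nrow(tab), 3 * 3 * 2)
    # masking problematic pairs improves the ranking of surviving edges
    # (medians over simulations; per-sim ordering is checked at larger
    # scale in the acceptance suite)
    med <- aggregate(auc ~ condition + sign, tab, median)
    for (sg in c("positive", "negative")) {
        expect_gte(med$auc[med$condition == "testability" &
                           med$sign == sg],
                   med$auc[med$condition == "none" & med$sign == sg])
    }
    # prevalence baseline removes at least as many pairs as testability
    nm <- aggregate(nCandidatePairs ~ condition + sim, tab, unique)
    for (s in unique(nm$sim)) {
        expect_lte(nm$nCandidatePairs[nm$condition == "prevalence" &
                                      nm$sim == s],
                   nm$nCandidatePairs[nm$condition == "testability" &
                                      nm$sim == s])
    }
    expect_true(all(tab$problematicFraction > 0.3))
})
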