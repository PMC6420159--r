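test_that("phi extrema match the brute-force contingency-table oracle", {
    # frozen examples (verified against the oracle below)
    expect_equal(unlist(phiExtrema(0.5, 0.5)), c(min = -1, max = 1))
    expect_equal(unlist(phiExtrema(0.3, 0.6)),
                 c(min = -0.8018, max = 0.5345), tolerance = 1e-4)
    expect_equal(unlist(phiExtrema(0.1, 0.1)), c(min = -1 / 9, max = 1))
    # closed form vs enumeration over integer-feasible tables: agreement
    # within the discretization gap of the integer co-occurrence grid
    for (n in c(11, 23, 50, 60)) {
        ab <- expand.grid(a = seq_len(n - 1), b = seq_len(n - 1))
        ext <- phiExtrema(ab$a / n, ab$b / n)
        for (r in seq(1, nrow(ab), by = 7)) {
            bf <- bruteForcePhiExtrema(ab$a[r], ab$b[r], n)
            pA <- ab$a[r] / n; pB <- ab$b[r] / n
            gap <- 1 / (n * sqrt(pA * (1 - pA) * pB * (1 - pB)))
            expect_lte(abs(ext$min[r] - bf["min"]), gap)
            expect_lte(abs(ext$max[r] - bf["max"]), gap)
            # closed form always at least as extreme as any feasible table
            expect_lte(ext$min[r], bf["min"] + 1e-12)
            expect_gte(ext$max[r], bf["max"] - 1e-12)
        }
    }
    expect_error(phiExtrema(0, 0.5), "between 0 and 1")
    expect_error(phiExtrema(0.5, 1), "between 0 and 1")
})

test_that("pearson minimum equals the disjoint-support worst case", {
    expect_equal(pearsonMin(0.2, 0.2), -0.25)
    expect_equal(pearsonMin(0.5, 0.5), -1)
    expect_equal(pearsonMin(0.05, 0.05), -0.0526, tolerance = 1e-3)
    n <- 1000
    for (a in c(50, 130, 320)) for (b in c(70, 260, 490)) {
        expect_equal(pearsonMin(a / n, b / n), worstCasePearson(a, b, n),
                     tolerance = 1e-9)
    }
    # beyond the disjoint-support regime the floor is -1
    expect_equal(pearsonMin(0.7, 0.6), -1)
})

test_that("critical values follow the chi-squared and Student quantiles", {
    expect_equal(phiCritical(50), 0.2772, tolerance = 1e-4)
    expect_equal(phiCritical(200), phiCritical(50) / 2)   # 1/sqrt(n) scaling
    expect_lt(phiCritical(50, alpha = 0.9999), 1e-2)
    expect_equal(rCritical(50), 0.2787, tolerance = 1e-4)
    expect_equal(rCritical(12), 0.5760, tolerance = 1e-4)
    expect_lt(rCritical(1e6), 2e-3)
    expect_error(phiCritical(2), "integer >= 3")
    expect_error(rCritical(50, alpha = 0), "between 0 and 1")
})

test_that("occurrence classification separates the four categories", {
    expect_equal(classifyOccurrence(0.1, 0.1, 50)$category, "positive_only")
    expect_equal(classifyOccurrence(0.5, 0.5, 50)$category, "full")
    # at equal prevalences max(phi) = 1, so the positive direction is
    # always testable however rare the OTUs are
    expect_equal(classifyOccurrence(0.02, 0.02, 50)$category,
                 "positive_only")
    # an unequal rare pair can be fully non-testable
    ext <- phiExtrema(0.04, 0.1)
    expect_true(max(abs(unlist(ext))) < phiCritical(50) ||
                classifyOccurrence(0.04, 0.1, 50)$category != "none")
})

test_that("abundance classification: positives always, negatives by floor", {
    v <- classifyAbundance(0.2, 0.2, 50)
    expect_true(v$positive_testable)
    expect_equal(v$category, "positive_only")     # floor -0.25 > -0.2787
    expect_equal(classifyAbundance(0.3, 0.3, 50)$category, "full")
    expect_equal(classifyAbundance(0.6, 0.6, 50)$category, "full")
    # nesting: negative testability at n persists for any larger n
    set.seed(11)
    for (r in 1:50) {
        pA <- runif(1, 0.02, 0.95); pB <- runif(1, 0.02, 0.95)
        n <- sample(5:200, 1)
        if (classifyAbundance(pA, pB, n)$negative_testable)
            expect_true(classifyAbundance(pA, pB, n + sample(1:500, 1)
                        )$negative_testable)
    }
})

test_that("fisher testability matches exact hypergeometric arithmetic", {
    expect_equal(fisherTestability(2, 2, 20)$category, "positive_only")
    # P(K = 2) = 1/190, P(K <= 0) = 153/190
    expect_equal(fisherTestability(10, 10, 20)$category, "full")
    # boundary p-value exactly alpha counts as testable: P(K = 1) = 1/20
    expect_equal(fisherTestability(1, 1, 20)$category, "positive_only")
    expect_equal(fisherTestability(1, 1, 21)$category, "positive_only")
    expect_equal(fisherTestability(1, 1, 19)$category, "none")
    expect_error(fisherTestability(0, 5, 20), "strictly between")
    expect_error(fisherTestability(20, 5, 20), "strictly between")
})

test_that("all classifiers are symmetric in the pair", {
    set.seed(3)
    for (r in 1:30) {
        pA <- runif(1, 0.02, 0.98); pB <- runif(1, 0.02, 0.98)
        n <- sample(10:300, 1)
        expect_identical(classifyOccurrence(pA, pB, n),
                         classifyOccurrence(pB, pA, n))
        expect_identical(classifyAbundance(pA, pB, n),
                         classifyAbundance(pB, pA, n))
        a <- sample(n - 1, 1); b <- sample(n - 1, 1)
        expect_identical(fisherTestability(a, b, n),
                         fisherTestability(b, a, n))
    }
})

test_that("fisher is at least as conservative as the phi rule at n = 50", {
    n <- 50
    ab <- expand.grid(a = seq_len(n - 1), b = seq_len(n - 1))
    phiV <- classifyOccurrence(ab$a / n, ab$b / n, n)
    fisV <- fisherTestability(ab$a, ab$b, n)
    expect_gte(sum(fisV$category == "none"), sum(phiV$category == "none"))
    expect_lte(sum(fisV$category %in% c("positive_only", "negative_only")),
               sum(phiV$category %in% c("positive_only", "negative_only")))
})

test_that("testability mask is symmetric and handles degenerate OTUs", {
    m <- testabilityMask(rep(0.5, 3), n = 50, mode = "abundance")
    cats <- maskCategories(m)
    expect_true(all(cats[upper.tri(cats)] == "full"))

    m2 <- testabilityMask(c(0.02, 0.02, 0.5), n = 50,
                          mode = "occurrence_phi")
    c2 <- maskCategories(m2)
    expect_equal(c2[1, 2], "positive_only")  # equal rare pair: max(phi)=1
    # unequal prevalences cap max(phi) at 0.143 < 0.277: fully untestable
    expect_equal(c2[1, 3], "none")
    expect_true(is.na(c2[2, 2]))
    e2 <- maskCategories(m2, encoded = TRUE)
    expect_identical(unname(e2[1, 2:3]), c(1L, 0L))  # positive_only, none

    set.seed(5)
    p <- runif(8, 0.05, 0.95)
    for (mode in c("occurrence_phi", "occurrence_fisher", "abundance")) {
        mm <- testabilityMask(p, n = 60, mode = mode)
        expect_identical(positiveTestable(mm), t(positiveTestable(mm)))
        expect_identical(negativeTestable(mm), t(negativeTestable(mm)))
    }

    expect_warning(md <- testabilityMask(c(0, 0.5, 0.6), n = 50),
                   "degenerate")
    expect_true(all(maskCategories(md)[1, -1] == "none"))
    # problematic = not fully testable
    pp <- problematicPairs(m2)
    expect_identical(unname(pp[1, 2]), TRUE)
    et <- edgeTable(m2)
    expect_equal(nrow(et), 3L)
    expect_named(et, c("otu_i", "otu_j", "positive_testable",
                       "negative_testable", "category"))
})
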