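test_that("normalization, zero rule and floor follow the workflow rules", {
    expect_identical(normalizeRPM(1, 1e6), 1)
    expect_identical(normalizeRPM(0, 1e6), 0)
    expect_equal(normalizeRPM(138637, 9.23e6), 15020.3, tolerance = 1e-5)
    expect_error(normalizeRPM(5, 0), "positive")

    expect_identical(applyZeroRule(0, 12.5), list(neA = 0.01, neB = 12.5))
    expect_identical(applyZeroRule(3.2, 4.1), list(neA = 3.2, neB = 4.1))
    expect_identical(applyZeroRule(0, 0), list(neA = 0.01, neB = 0.01))

    expect_true(expressionFloor(0.01, 250))
    expect_false(expressionFloor(0.4, 0.7))
    expect_true(expressionFloor(1.0, 0.01))   # boundary is inclusive
})

test_that("fold changes reproduce the published worked examples", {
    expect_identical(foldChange(10, 10), 0)
    # miR-21: counts 138637 vs 43703, depths 9.23M vs 11.01M
    fc21 <- foldChange(normalizeRPM(138637, 9.23e6),
                       normalizeRPM(43703, 11.01e6))
    expect_lt(abs(fc21 - 1.92), 0.01)
    # let-7a, same depths
    fc7a <- foldChange(normalizeRPM(247959, 9.23e6),
                       normalizeRPM(2356002, 11.01e6))
    expect_lt(abs(fc7a - (-2.99)), 0.02)
    expect_error(foldChange(0, 1), "positive")
    # anti-symmetry
    set.seed(2)
    a <- runif(20, 0.01, 1e4); b <- runif(20, 0.01, 1e4)
    expect_equal(foldChange(a, b), -foldChange(b, a), tolerance = 1e-12)
})

test_that("significance labels follow the two-band rule", {
    expect_identical(labelSignificance(1.92, 0.001), "**")
    expect_identical(labelSignificance(0.5, 1e-9), "none")
    expect_identical(labelSignificance(-1.5, 0.03), "*")
    expect_identical(labelSignificance(-1.5, 0.01), "*")   # boundary
    expect_identical(labelSignificance(1.5, 0.05), "none")
    expect_identical(labelSignificance(1.0, 0.001), "none")  # |fc| not > 1
})

test_that("categories and percentages match the reporting conventions", {
    expect_identical(categorize(10, 0), "A-specific")
    expect_identical(categorize(0, 7), "B-specific")
    expect_identical(categorize(3, 9), "co-expressed")

    expect_identical(percentOf(471, 617), 76.34)
    expect_identical(percentOf(407, 617), 65.96)
    expect_identical(percentOf(90, 617), 14.59)
    expect_identical(percentOf(0, 617), 0)
    expect_error(percentOf(1, 0), "positive")
    expect_error(percentOf(8, 7), "part")
})

test_that("the per-entity analysis table is internally consistent", {
    mature <- matrix(c(138637L, 247959L, 0L, 40L,
                       43703L, 2356002L, 9L, 0L), 4, 2,
                     dimnames = list(c("miR-21", "let-7a", "mir-bonly",
                                       "mir-aonly"), c("A", "B")))
    star <- matrix(c(179L, 47L, 0L, 0L,
                     81L, 51L, 0L, 0L), 4, 2,
                   dimnames = dimnames(mature))
    mcs <- MirnaCountSet(mature, star, c(9.23e6, 11.01e6))
    res <- mirnaDiffExpr(mcs, "A", "B")

    r21 <- res[res$id == "miR-21" & res$arm == "mature", ]
    expect_lt(abs(r21$foldChange - 1.92), 0.01)
    expect_identical(r21$sigLabel, "**")
    expect_identical(r21$category, "co-expressed")

    aonly <- res[res$id == "mir-aonly", ]
    expect_identical(aonly$category, "A-specific")
    expect_true(aonly$included)     # 0 count became 0.01 RPM, other > 1
    expect_equal(aonly$neB, 0.01)

    # star entities carry the * suffix
    expect_true("miR-21*" %in% res$id)
    # labels always consistent with the rule
    expect_identical(res$sigLabel,
                     labelSignificance(res$foldChange, res$pValue))
    # p-values from raw counts, not substituted NE
    expect_equal(res[res$id == "miR-21" & res$arm == "mature", "pValue"],
                 acPvalue(138637, 43703, 9.23e6, 11.01e6))
})

test_that("category summary counts and tallies the significant records", {
    mature <- matrix(c(1000L, 0L, 300L, 500L,
                       100L, 80L, 0L, 480L), 4, 2,
                     dimnames = list(paste0("m", 1:4), c("A", "B")))
    star <- matrix(0L, 4, 2, dimnames = dimnames(mature))
    mcs <- MirnaCountSet(mature, star, c(1e6, 1e6))
    res <- mirnaDiffExpr(mcs)
    s <- categorySummary(res)
    expect_identical(s$nTotal, 4L)
    expect_identical(s$nCoexpressed, 2L)
    expect_identical(s$nASpecific, 1L)
    expect_identical(s$nBSpecific, 1L)
    expect_identical(s$pctCoexpressed, percentOf(2, 4))
    expect_identical(s$nUp, s$nUpASpecific + s$nUpCoexpressed)
    expect_identical(s$nDown, s$nDownBSpecific + s$nDownCoexpressed)
    # m1 is strongly up, m3 A-specific up, m2 B-specific down
    expect_gte(s$nUp, 2L)
    expect_gte(s$nDown, 1L)
})

test_that("top expressed entities are ranked by the chosen library", {
    mature <- matrix(c(5L, 3L, 9L, 1L, 8L, 2L), 3, 2,
                     dimnames = list(c("a", "b", "c"), c("A", "B")))
    star <- matrix(0L, 3, 2, dimnames = dimnames(mature))
    mcs <- MirnaCountSet(mature, star, c(100, 100))
    res <- mirnaDiffExpr(mcs)
    expect_identical(topExpressed(res, "A", 3)$id, c("c", "a", "b"))
    expect_identical(topExpressed(res, "B", 2)$id, c("b", "c"))
    expect_identical(nrow(topExpressed(res, "A", 1)), 1L)
    expect_error(topExpressed(res, "A", 0), ">= 1")
})

test_that("the null exact test is conservative but not degenerate", {
    # Poisson null calibration at a moderate rate (smoke-scale; the
    # acceptance suite runs the full grid)
    set.seed(31)
    n <- 2000
    x <- rpois(n, 50); y <- rpois(n, 50)
    p <- acPvalue(x, y, 1e6, 1e6)
    rate <- mean(p < 0.05)
    expect_gte(rate, 0.005)
    expect_lte(rate, 0.07)
})
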