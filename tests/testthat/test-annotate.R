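test_that("tag matching handles identity, excess mismatches and shifts", {
    flip <- function(s, p) {
        substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, p, p))[1]
        s
    }
    ref <- "ACGGTTCAAGCTTGACCATGTC"
    hit <- matchTag(ref, ref)
    expect_identical(hit$nMismatches, 0L)
    expect_identical(hit$offset, 0L)

    tag3 <- flip(flip(flip(ref, 2), 9), 15)
    expect_null(matchTag(tag3, ref))        # 3 substitutions exceed maxSub

    # shift +1 with one substitution
    tag <- flip(substr(ref, 2, nchar(ref)), 5)
    hit <- matchTag(tag, ref)
    expect_identical(hit$nMismatches, 1L)
    expect_identical(hit$offset, 1L)

    expect_error(matchTag("", ref), "empty")
    # U is treated as T
    expect_identical(matchTag(chartr("T", "U", ref), ref)$nMismatches, 0L)
})

test_that("tag matching agrees with the brute-force alignment oracle", {
    set.seed(19)
    bases <- c("A", "C", "G", "T")
    refs <- vapply(1:5, function(i)
        paste(sample(bases, 22, TRUE), collapse = ""), "")
    for (i in 1:150) {
        k <- sample(5, 1)
        s <- sample(-2:2, 1)
        ref <- refs[k]
        lt <- sample(19:23, 1)
        start <- max(1, 1 + s)
        tag <- substr(ref, start, min(nchar(ref), start + lt - 1))
        nmm <- sample(0:3, 1)
        for (j in seq_len(nmm)) {
            p <- sample(nchar(tag), 1)
            substr(tag, p, p) <- sample(setdiff(bases, substr(tag, p, p)), 1)
        }
        want <- bruteMatch(tag, refs)
        # the multi-reference path used by classifyTags
        hit <- miRPair:::match_tags_best(tag, refs, 2L, 2L)
        if (is.null(want)) {
            expect_identical(hit[1, 1], 0L, info = tag)
        } else {
            expect_identical(hit[1, 1], want$ref, info = tag)
            expect_identical(hit[1, 2], want$m, info = tag)
            expect_identical(hit[1, 3], want$s, info = tag)
        }
    }
})

test_that("classification follows priority and annotates the truth exactly", {
    sim <- smallExperiment(seed = 5, zeroNoise = TRUE)
    A <- annotateLib(sim$libA, sim$specA, sim)
    an <- A$annot

    # zero-noise: every miRNA-derived tag correctly assigned
    arms <- c(as.character(matureSeqs(sim$catalog)),
              as.character(starSeqs(sim$catalog)))
    isMir <- an$rnaClass %in% c("miRNA", "miRNA_star")
    expect_true(all(an$seq[isMir] %in% arms))
    expect_true(all(an$nMismatches[isMir] == 0L))

    # a tag matching both an rRNA and a miRNA is classed rRNA by priority
    rseq <- as.character(sim$contaminants$rRNA[[1]])
    tag <- substr(rseq, 3, 24)
    fake <- collapseReads(c(tag, tag))
    cls <- classifyTags(fake, sim$catalog,
                        c(sim$contaminants,
                          list(miRNAlike = Biostrings::DNAStringSet(tag))))
    expect_identical(as.character(cls$rnaClass[1]), "rRNA")

    # unknown priority class is a configuration error
    expect_error(classifyTags(fake, sim$catalog, sim$contaminants,
                              priority = c("rRNA", "mystery")),
                 "unknown class")

    # random tag matching nothing is unannotated
    none <- classifyTags(collapseReads("TTAACCGGTTAACCGG"),
                         sim$catalog, sim$contaminants)
    expect_identical(as.character(none$rnaClass[1]), "unannotated")
})

test_that("classification does not depend on tag input order", {
    sim <- smallExperiment(seed = 6, zeroNoise = FALSE, nReads = 3000)
    A <- annotateLib(sim$libA, sim$specA, sim)
    tags <- collapseReads(A$clean$reads)
    perm <- tags[rev(seq_len(nrow(tags))), ]
    an1 <- classifyTags(tags, sim$catalog, sim$contaminants)
    an2 <- classifyTags(perm, sim$catalog, sim$contaminants)
    o1 <- order(an1$seq); o2 <- order(an2$seq)
    expect_identical(as.data.frame(an1[o1, ]), as.data.frame(an2[o2, ]))
})

test_that("zero-noise aggregation reproduces the truth table exactly", {
    sim <- smallExperiment(seed = 5, zeroNoise = TRUE)
    A <- annotateLib(sim$libA, sim$specA, sim)
    B <- annotateLib(sim$libB, sim$specB, sim)
    mcs <- aggregateMirnaCounts(list(A = A$annot, B = B$annot),
                                c(A$clean$stats@cleanTotal,
                                  B$clean$stats@cleanTotal))
    tr <- sim$truth
    det <- tr[tr$matureA + tr$matureB + tr$starA + tr$starB > 0, ]
    expect_setequal(rownames(mcs), det$id)
    m <- match(det$id, rownames(mcs))
    expect_identical(unname(matureCounts(mcs)[m, "A"]), det$matureA)
    expect_identical(unname(matureCounts(mcs)[m, "B"]), det$matureB)
    expect_identical(unname(starCounts(mcs)[m, "A"]), det$starA)
    expect_identical(unname(starCounts(mcs)[m, "B"]), det$starB)
})

test_that("count aggregation sums tags per arm and omits empty miRNAs", {
    an <- S4Vectors::DataFrame(
        seq = c("a", "b", "c"), count = c(5L, 7L, 3L),
        rnaClass = factor(c("miRNA", "miRNA", "miRNA_star"),
                          levels = c("miRNA", "miRNA_star",
                                     "unannotated")),
        assignedId = c("mir-X", "mir-X", "mir-Y"),
        nMismatches = 0L, offset = 0L)
    empty <- an[0, ]
    mcs <- aggregateMirnaCounts(list(A = an, B = empty), c(100, 100))
    expect_identical(unname(matureCounts(mcs)["mir-X", "A"]), 12L)
    expect_identical(unname(starCounts(mcs)["mir-Y", "A"]), 3L)
    expect_identical(unname(matureCounts(mcs)["mir-Y", "B"]), 0L)
    expect_identical(sort(rownames(mcs)), c("mir-X", "mir-Y"))
})

test_that("duplex pairs require both arms in the same library", {
    mature <- matrix(c(10L, 439L, 0L, 2356002L), 2, 2,
                     dimnames = list(c("mir-a", "miR-199b"),
                                     c("A", "B")))
    star <- matrix(c(0L, 39305L, 5L, 194315L), 2, 2,
                   dimnames = dimnames(mature))
    mcs <- MirnaCountSet(mature, star, c(9.23e6, 11.01e6))
    dp <- findDuplexPairs(mcs)
    # mir-a: mature only in A, star only in B -> never a pair
    expect_false("mir-a" %in% dp$id)
    # star-dominant pair detected in both libraries
    expect_identical(sum(dp$id == "miR-199b"), 2L)
})

test_that("planted star-expressing miRNAs are recovered as duplex pairs", {
    sim <- smallExperiment(seed = 9, zeroNoise = TRUE)
    A <- annotateLib(sim$libA, sim$specA, sim)
    B <- annotateLib(sim$libB, sim$specB, sim)
    mcs <- aggregateMirnaCounts(list(A = A$annot, B = B$annot),
                                c(A$clean$stats@cleanTotal,
                                  B$clean$stats@cleanTotal))
    dp <- findDuplexPairs(mcs)
    tr <- sim$truth
    wantA <- tr$id[tr$matureA > 0 & tr$starA > 0]
    expect_setequal(dp$id[dp$library == "A"], wantA)
})

test_that("composition fractions partition reads and unique tags", {
    sim <- smallExperiment(seed = 7, zeroNoise = FALSE, nReads = 4000)
    A <- annotateLib(sim$libA, sim$specA, sim)
    comp <- compositionSummary(A$annot)
    base <- comp[!comp$merged, ]
    expect_equal(sum(base$readFraction), 1, tolerance = 1e-12)
    expect_equal(sum(base$uniqueFraction), 1, tolerance = 1e-12)
    expect_equal(sum(base$reads), sum(A$annot$count))
    expect_equal(sum(base$reads), A$clean$stats@cleanTotal)
    merged <- comp[comp$merged, ]
    mir <- base[base$class %in% c("miRNA", "miRNA_star"), ]
    expect_equal(merged$readFraction, sum(mir$readFraction))

    # all-miRNA degenerate case
    an <- A$annot[A$annot$rnaClass == "miRNA", ]
    comp2 <- compositionSummary(an)
    expect_equal(comp2$readFraction[comp2$class == "miRNA"], 1)
    expect_equal(comp2$uniqueFraction[comp2$class == "miRNA"], 1)
})

test_that("sampled contaminant fraction matches its mixture probability", {
    ref <- generateCatalog(30, 4, seed = 21)
    spec <- librarySpec(20000, contaminantFraction = 0.05, errorRate = 0,
                        adapter5Fraction = 0, lowQualityFraction = 0,
                        seed = 22)
    lib <- simulateLibrary(ref$catalog, spec, ref$contaminants)
    cl <- cleanReads(list(sequences = lib$sequences,
                          qualities = lib$qualities), spec@adapter)
    an <- classifyTags(collapseReads(cl$reads), ref$catalog,
                       ref$contaminants)
    comp <- compositionSummary(an)
    contam <- sum(comp$readFraction[comp$class %in%
        c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")])
    expect_lt(abs(contam - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
})
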