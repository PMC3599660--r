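ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming finds exact, absent and mismatched adapters", {
    expect_identical(trimAdapter(paste0("ACGTACGT", "TGGAATTC"),
                                 "TGGAATTC"), "ACGTACGT")
    expect_identical(trimAdapter("ACGTACGT", "TGGAATTC"),
                     NA_character_)
    # one substitution within an 8 nt adapter at rate 0.15
    read <- paste0("ACGTACGTACGT", "TGGATTTC")
    expect_identical(trimAdapter(read, "TGGAATTC",
                                 maxMismatchRate = 0.15), "ACGTACGTACGT")
    expect_error(trimAdapter("ACGT", "ACG", minOverlap = 6),
                 "at least minOverlap")
})

test_that("adapter trimming matches the enumeration oracle", {
    set.seed(42)
    bases <- c("A", "C", "G", "T")
    for (i in 1:200) {
        insert <- paste(sample(bases, sample(10:28, 1), TRUE),
                        collapse = "")
        alen <- sample(6:nchar(ADAPTER), 1)     # possibly truncated
        ad <- substr(ADAPTER, 1, alen)
        read <- paste0(insert, ad)
        if (i %% 3 == 0) {                       # inject a mismatch
            p <- sample(nchar(read), 1)
            substr(read, p, p) <- sample(setdiff(bases,
                substr(read, p, p)), 1)
        }
        expect_identical(trimAdapter(read, ADAPTER),
                         bruteTrim(read, ADAPTER),
                         info = read)
    }
})

test_that("re-appending the adapter and trimming again is a fixed point", {
    set.seed(7)
    inserts <- vapply(1:50, function(i)
        paste(sample(c("A", "C", "G", "T"), sample(15:30, 1), TRUE),
              collapse = ""), "")
    once <- trimAdapter(paste0(inserts, ADAPTER), ADAPTER)
    twice <- trimAdapter(paste0(once, ADAPTER), ADAPTER)
    expect_identical(once, twice)
})

test_that("cleaning keeps fully clean reads and accounts for each filter", {
    inserts <- strrep(c("ACGTA"), 1)
    seqs <- paste0(strrep("ACGT", 5), ADAPTER)        # 20 nt inserts
    fq <- list(sequences = rep(seqs, 100),
               qualities = rep(strrep("I", nchar(seqs)), 100))
    out <- cleanReads(fq, ADAPTER)
    expect_identical(out$stats@cleanTotal, 100L)
    expect_identical(out$stats@removedLowQuality, 0L)
    expect_identical(out$stats@removedNoAdapter, 0L)
    expect_identical(out$stats@removedLength, 0L)
    expect_true(all(out$reads == strrep("ACGT", 5)))

    # a read trimmed to 14 nt falls below the length window
    short <- paste0(strrep("AC", 7), ADAPTER)
    out2 <- cleanReads(list(sequences = short,
                            qualities = strrep("I", nchar(short))),
                       ADAPTER)
    expect_identical(out2$stats@removedLength, 1L)
    expect_identical(out2$stats@cleanTotal, 0L)

    # pure adapter reads also count as length removals
    out3 <- cleanReads(list(sequences = ADAPTER,
                            qualities = strrep("I", nchar(ADAPTER))),
                       ADAPTER)
    expect_identical(out3$stats@removedLength, 1L)
})

test_that("planted low-quality reads are removed at the expected rate", {
    ref <- generateCatalog(10, 2, seed = 3)
    spec <- librarySpec(20000, lowQualityFraction = 0.1, seed = 11)
    lib <- simulateLibrary(ref$catalog, spec, ref$contaminants)
    out <- cleanReads(list(sequences = lib$sequences,
                           qualities = lib$qualities), spec@adapter)
    frac <- out$stats@removedLowQuality / out$stats@totalRaw
    expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))
    # full accounting
    expect_true(validObject(out$stats))
    expect_identical(out$stats@totalRaw,
                     out$stats@cleanTotal + out$stats@removedLowQuality +
                     out$stats@removedAdapter5 +
                     out$stats@removedNoAdapter + out$stats@removedLength)
})

test_that("malformed FASTQ errors name the record index", {
    fp <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "IIII",
                 "@r2", "ACGTA", "+", "III"), fp)   # quality too short
    expect_error(readFastq(fp), "record at index 2")
})

test_that("collapsing conserves counts, is idempotent and order-invariant", {
    expect_identical(as.data.frame(collapseReads(c("AAA", "AAA", "CCC"))),
                     data.frame(seq = c("AAA", "CCC"), count = c(2L, 1L)))
    expect_identical(nrow(collapseReads(character(0))), 0L)

    set.seed(3)
    reads <- sample(c("ACGTACGTACGTACG", "TTTTACGTACGTACG",
                      "GGGGACGTACGTACG", "CCCCACGTACGTACG"),
                    1e4, TRUE, prob = c(0.5, 0.3, 0.15, 0.05))
    tags <- collapseReads(reads)
    expect_identical(sum(tags$count), 10000L)
    # descending counts, ties lexicographic
    expect_true(all(diff(tags$count) <= 0))
    # order invariance
    tags2 <- collapseReads(rev(reads))
    expect_identical(as.data.frame(tags), as.data.frame(tags2))
    # idempotence on its own support
    expect_identical(collapseReads(tags$seq)$seq, sort(tags$seq))
})

test_that("length distribution sums to one with the planted mode", {
    expect_identical(lengthDistribution(rep(strrep("A", 22), 5)),
                     c("22" = 1))
    d <- lengthDistribution(c(strrep("A", 21), strrep("C", 21),
                              strrep("G", 24)))
    expect_equal(unname(d), c(2 / 3, 1 / 3))
    expect_error(lengthDistribution(character(0)), "empty")

    ref <- generateCatalog(30, 2, seed = 6)
    spec <- librarySpec(20000, seed = 13)
    lib <- simulateLibrary(ref$catalog, spec, ref$contaminants)
    out <- cleanReads(list(sequences = lib$sequences,
                           qualities = lib$qualities), spec@adapter)
    ld <- lengthDistribution(out$reads)
    expect_equal(sum(ld), 1, tolerance = 1e-12)
    mode <- as.integer(names(ld)[which.max(ld)])
    expect_identical(mode, 22L)
})
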