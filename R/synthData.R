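# Synthetic reference catalog and read-library simulator. The simulator is
# first-class, tested code: it provides the known truth against which every
# downstream stage is validated.

.BASES <- c("A", "C", "G", "T")

# n random DNA sequences with the given lengths (vectorized)
.randSeq <- function(lens) {
    if (length(lens) == 0L) return(character(0))
    chars <- sample(.BASES, sum(lens), replace = TRUE)
    grp <- factor(rep.int(seq_along(lens), lens), levels = seq_along(lens))
    out <- vapply(split(chars, grp), paste0, collapse = "", FUN.VALUE = "")
    names(out) <- NULL
    out[lens == 0L] <- ""
    out
}

# substitute k random positions of seq (positions limited to 1..maxPos)
.plantMismatches <- function(seq, k, maxPos = nchar(seq)) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- sample.int(maxPos, k)
    for (p in pos) ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
    paste0(ch, collapse = "")
}

.revcomp <- function(x) as.character(reverseComplement(DNAStringSet(x)))

#' Generate a synthetic hairpin catalog and contaminant references
#'
#' Builds \code{nMirnas} precursor hairpins of 60-80 nt. Each hairpin
#' carries a 20-24 nt mature arm and a star arm on the opposite side of the
#' loop; the star arm is the reverse complement of the mature arm shifted
#' by the 2 nt overhang of a Dicer-like duplex and carrying 1-3 planted
#' mismatches, so the two arms form a duplex-like imperfect pair.
#' Contaminant references are random sequences for five ncRNA classes
#' (rRNA, tRNA, snRNA, snoRNA, repeat) with lengths well outside the
#' 21-24 nt miRNA range.
#'
#' @param nMirnas Number of hairpins (>= 1).
#' @param nContaminantsPerClass Reference sequences per contaminant class
#'   (>= 1).
#' @param seed Integer seed; the output is byte-identical for a fixed seed.
#' @return A list with \code{catalog} (a [HairpinCatalog-class]) and
#'   \code{contaminants} (a named list of \link[Biostrings]{DNAStringSet},
#'   one per class).
#' @examples
#' ref <- generateCatalog(10, nContaminantsPerClass = 3, seed = 1)
#' ref$catalog
#' lengths(ref$contaminants)
#' @export
generateCatalog <- function(nMirnas, nContaminantsPerClass = 5, seed = 1L) {
    if (nMirnas < 1L || nContaminantsPerClass < 1L)
        stop("nMirnas and nContaminantsPerClass must be positive")
    with_seed(as.integer(seed), {
        ids <- sprintf("syn-mir-%03d", seq_len(nMirnas))
        hair <- character(nMirnas)
        a5s <- a3s <- integer(nMirnas)
        w5 <- w3 <- integer(nMirnas)
        matArm <- sample(c("5p", "3p"), nMirnas, replace = TRUE)
        for (i in seq_len(nMirnas)) {
            # Dicer products peak at 22 nt
            lm <- sample(20:24, 1L, prob = c(0.05, 0.2, 0.5, 0.2, 0.05))
            mature <- .randSeq(lm)
            # duplex partner: reverse complement with 2 nt overhang offset,
            # trailing bases refilled, then 1-3 planted mismatches
            rc <- .revcomp(mature)
            star <- paste0(substr(rc, 3L, lm), .randSeq(2L))
            star <- .plantMismatches(star, sample(1:3, 1L), maxPos = lm - 2L)
            if (matArm[i] == "5p") { s5 <- mature; s3 <- star }
            else                   { s5 <- star;   s3 <- mature }
            loop <- .randSeq(sample(10:16, 1L))
            f5 <- sample(0:3, 1L)
            base <- f5 + nchar(s5) + nchar(loop) + nchar(s3)
            f3 <- sample(max(0L, 60L - base):(80L - base), 1L)
            hair[i] <- paste0(.randSeq(f5), s5, loop, s3, .randSeq(f3))
            a5s[i] <- f5 + 1L; w5[i] <- nchar(s5)
            a3s[i] <- f5 + nchar(s5) + nchar(loop) + 1L; w3[i] <- nchar(s3)
        }
        dss <- DNAStringSet(hair)
        names(dss) <- ids
        catalog <- HairpinCatalog(
            hairpins = dss,
            arm5p = IRanges(a5s, width = w5),
            arm3p = IRanges(a3s, width = w3),
            matureArm = matArm)
        lenRange <- list(rRNA = 90:150, tRNA = 70:90, snRNA = 100:140,
                         snoRNA = 60:110, repeat_ = 50:150)
        contaminants <- lapply(names(lenRange), function(cls) {
            lens <- sample(lenRange[[cls]], nContaminantsPerClass,
                           replace = TRUE)
            s <- DNAStringSet(.randSeq(lens))
            names(s) <- sprintf("%s_%d", sub("_$", "", cls),
                                seq_len(nContaminantsPerClass))
            s
        })
        names(contaminants) <- sub("_$", "", names(lenRange))
        list(catalog = catalog, contaminants = contaminants)
    })
}

# per-base substitution errors at the given rate
.mutateSeqs <- function(seqs, rate) {
    if (rate <= 0) return(seqs)
    lens <- nchar(seqs)
    nerr <- rbinom(length(seqs), lens, rate)
    idx <- which(nerr > 0L)
    for (i in idx)
        seqs[i] <- .plantMismatches(seqs[i], nerr[i])
    seqs
}

#' Simulate one raw small RNA read library
#'
#' Emits \code{nReads} reads from a mixture of sources: miRNA arms (mature
#' or star, chosen per hairpin with probability proportional to a
#' log-normal abundance times the planted effect), contaminant ncRNA
#' fragments, uniform random ("unannotated") sequences, and 5'-adapter
#' contaminant reads. Each insert gets 3' length jitter (miRNA reads only),
#' per-base substitution errors, and the 3' adapter appended; a fraction of
#' reads is overlaid with failing base qualities. Reads are emitted 5'->3'
#' on the sense strand of the arm (single-stranded library chemistry).
#'
#' @param catalog A [HairpinCatalog-class].
#' @param spec A [LibrarySpec-class].
#' @param contaminants Named list of \link[Biostrings]{DNAStringSet}
#'   contaminant references (required when
#'   \code{contaminantFraction > 0}).
#' @param fastqPath Optional path; when given the library is also written
#'   as Sanger-encoded FASTQ.
#' @return A list with \code{sequences}, \code{qualities} (character
#'   vectors), and \code{truth}, a \code{DataFrame} with per-miRNA columns
#'   \code{id}, \code{matureCount}, \code{starCount}, \code{log2Effect},
#'   \code{absent}; its \code{metadata()} records the contaminant,
#'   unannotated, 5'-contaminant and low-quality read counts.
#' @examples
#' ref <- generateCatalog(5, 2, seed = 1)
#' lib <- simulateLibrary(ref$catalog, librarySpec(500, seed = 3),
#'                        ref$contaminants)
#' sum(lib$truth$matureCount) + sum(lib$truth$starCount) +
#'   sum(unlist(metadata(lib$truth)[c("nContaminant", "nUnannotated",
#'                                    "nAdapter5")]))
#' @export
simulateLibrary <- function(catalog, spec, contaminants = NULL,
                            fastqPath = NULL) {
    stopifnot(is(catalog, "HairpinCatalog"), is(spec, "LibrarySpec"))
    validObject(spec)
    n <- length(catalog)
    if (n == 0L) stop("catalog is empty")
    ids <- names(catalog)
    bad <- setdiff(c(names(spec@deEffects), spec@specificAbsent), ids)
    if (length(bad))
        stop("unknown miRNA ids in spec: ", paste(bad, collapse = ", "))

    # shared baseline abundances, then library-specific effects
    lambda <- with_seed(spec@abundanceSeed,
        rlnorm(n, spec@abundanceMu, spec@abundanceSigma))
    eff <- setNames(rep(0, n), ids)
    eff[names(spec@deEffects)] <- spec@deEffects
    w <- lambda * 2^eff
    w[ids %in% spec@specificAbsent] <- 0

    mirnaFrac <- max(0, 1 - spec@contaminantFraction -
        spec@unannotatedFraction - spec@adapter5Fraction)
    if (mirnaFrac > 0 && sum(w) == 0)
        stop("all miRNA abundances are zero but miRNA reads are requested")
    if (spec@contaminantFraction > 0 &&
        (is.null(contaminants) || !length(contaminants)))
        stop("contaminant references required when contaminantFraction > 0")

    hairChr <- as.character(hairpins(catalog))
    matureIs5p <- matureArm(catalog) == "5p"
    s5 <- start(arm5p(catalog)); e5 <- end(arm5p(catalog))
    s3 <- start(arm3p(catalog)); e3 <- end(arm3p(catalog))
    armStart <- function(mi, star) {
        use5p <- xor(matureIs5p[mi], star)    # star reads use opposite arm
        ifelse(use5p, s5[mi], s3[mi])
    }
    armEnd <- function(mi, star) {
        use5p <- xor(matureIs5p[mi], star)
        ifelse(use5p, e5[mi], e3[mi])
    }

    with_seed(spec@seed, {
        nr <- spec@nReads
        src <- sample(c("mirna", "contam", "unann", "ad5"), nr,
                      replace = TRUE,
                      prob = c(mirnaFrac, spec@contaminantFraction,
                               spec@unannotatedFraction,
                               spec@adapter5Fraction))
        inserts <- character(nr)
        mi <- integer(nr)
        isStar <- logical(nr)

        iM <- which(src == "mirna")
        if (length(iM)) {
            mi[iM] <- sample.int(n, length(iM), replace = TRUE, prob = w)
            isStar[iM] <- runif(length(iM)) < spec@starFraction
            d <- sample(-2:2, length(iM), replace = TRUE,
                        prob = spec@jitterProb)
            st <- armStart(mi[iM], isStar[iM])
            en <- pmin(armEnd(mi[iM], isStar[iM]) + d,
                       nchar(hairChr)[mi[iM]])
            inserts[iM] <- substr(hairChr[mi[iM]], st, en)
        }
        iC <- which(src == "contam")
        if (length(iC)) {
            allC <- unlist(lapply(contaminants, as.character),
                           use.names = FALSE)
            ci <- sample.int(length(allC), length(iC), replace = TRUE)
            fl <- sample(c(15:19, 25:30), length(iC), replace = TRUE)
            fl <- pmin(fl, nchar(allC)[ci])
            stc <- 1L + floor(runif(length(iC)) * (nchar(allC)[ci] - fl + 1L))
            inserts[iC] <- substr(allC[ci], stc, stc + fl - 1L)
        }
        iU <- which(src == "unann")
        if (length(iU))
            inserts[iU] <- .randSeq(sample(15:25, length(iU),
                                           replace = TRUE))
        iA <- which(src == "ad5")
        if (length(iA))
            inserts[iA] <- paste0(
                substr(spec@adapter5, 1L,
                       min(18L, nchar(spec@adapter5))),
                .randSeq(sample(8:12, length(iA), replace = TRUE)))

        reads <- .mutateSeqs(paste0(inserts, spec@adapter), spec@errorRate)
        quals <- strrep("I", nchar(reads))
        if (spec@lowQualityFraction > 0) {
            lq <- runif(nr) < spec@lowQualityFraction
            quals[lq] <- strrep("#", nchar(reads)[lq])
            nLowQual <- sum(lq)
        } else nLowQual <- 0L

        truth <- DataFrame(
            id = ids,
            matureCount = tabulate(mi[iM][!isStar[iM]], nbins = n),
            starCount = tabulate(mi[iM][isStar[iM]], nbins = n),
            log2Effect = unname(eff),
            absent = ids %in% spec@specificAbsent)
        metadata(truth) <- list(
            nReads = nr,
            nContaminant = length(iC),
            nUnannotated = length(iU),
            nAdapter5 = length(iA),
            nLowQuality = nLowQual)

        if (!is.null(fastqPath))
            writeFastq(reads, quals, fastqPath)
        list(sequences = reads, qualities = quals, truth = truth)
    })
}

#' Simulate a paired two-library experiment with planted truth
#'
#' Convenience wrapper that draws one catalog, one shared baseline
#' abundance profile, and two libraries: library A ("treatment", e.g.
#' pregnant) receives planted log2 effects of \code{+/- deLog2FC} on
#' \code{nDE} miRNAs whose expected mature count is at least
#' \code{minExpectedCount}; \code{nSpecificA}/\code{nSpecificB} further
#' miRNAs are forced absent from the opposite library. With
#' \code{zeroNoise = TRUE} all corruption is switched off (no substitution
#' errors, no length jitter, no contaminant/unannotated/5'-contaminant
#' reads, no low-quality overlay), so downstream annotation must recover
#' the truth table exactly.
#'
#' @param nMirnas,nReads Catalog size and per-library read count.
#' @param nDE Number of planted differentially expressed miRNAs (half up,
#'   half down in library A).
#' @param deLog2FC Absolute planted log2 fold change.
#' @param nSpecificA,nSpecificB Library-specific miRNAs (absent from B and
#'   A respectively).
#' @param minExpectedCount Eligibility floor (expected mature reads) for
#'   planted DE miRNAs.
#' @param seed Integer master seed.
#' @param zeroNoise Switch off all read corruption.
#' @param nContaminantsPerClass Contaminant references per class.
#' @param ... Further arguments passed to [librarySpec()] (both libraries).
#' @return A list with \code{catalog}, \code{contaminants}, \code{specA},
#'   \code{specB}, \code{libA}, \code{libB} and \code{truth}, a
#'   \code{DataFrame} with per-miRNA counts in both libraries, the planted
#'   effect, DE flag, specificity, and the expression category implied by
#'   the emitted counts (\code{co-expressed}, \code{A-specific},
#'   \code{B-specific}, \code{undetected}).
#' @examples
#' sim <- simulateExperiment(nMirnas = 20, nReads = 2000, nDE = 4,
#'                           nSpecificA = 1, nSpecificB = 1,
#'                           minExpectedCount = 20, seed = 1)
#' table(sim$truth$category)
#' @export
simulateExperiment <- function(nMirnas = 200, nReads = 1e5, nDE = 20,
                               deLog2FC = 2, nSpecificA = 5, nSpecificB = 5,
                               minExpectedCount = 100, seed = 1L,
                               zeroNoise = FALSE,
                               nContaminantsPerClass = 8, ...) {
    seed <- as.integer(seed)
    ref <- generateCatalog(nMirnas, nContaminantsPerClass, seed = seed)
    ids <- names(ref$catalog)

    extra <- list(...)
    specArgs <- c(list(nReads = nReads, abundanceSeed = seed), extra)
    if (zeroNoise)
        specArgs[c("errorRate", "contaminantFraction",
                   "unannotatedFraction", "adapter5Fraction",
                   "lowQualityFraction")] <- list(0, 0, 0, 0, 0)
    if (zeroNoise) specArgs$jitterProb <- c(0, 0, 1, 0, 0)
    probe <- do.call(librarySpec, c(specArgs, list(seed = seed)))

    # reproduce the baseline abundance draw to pick eligible DE miRNAs
    lambda <- with_seed(seed,
        rlnorm(nMirnas, probe@abundanceMu, probe@abundanceSigma))
    mirnaFrac <- 1 - probe@contaminantFraction -
        probe@unannotatedFraction - probe@adapter5Fraction
    expMature <- nReads * mirnaFrac * (1 - probe@starFraction) *
        lambda / sum(lambda)

    sel <- with_seed(seed + 1L, {
        eligible <- ids[expMature >= minExpectedCount]
        if (length(eligible) < nDE)
            stop("not enough miRNAs reach minExpectedCount; ",
                 "increase nReads or lower the floor")
        deIds <- sample(eligible, nDE)
        pool <- setdiff(ids[expMature >= 20], deIds)
        if (length(pool) < nSpecificA + nSpecificB)
            stop("not enough miRNAs for the library-specific sets")
        spc <- sample(pool, nSpecificA + nSpecificB)
        list(deIds = deIds,
             aSpecific = spc[seq_len(nSpecificA)],
             bSpecific = spc[nSpecificA + seq_len(nSpecificB)])
    })
    effects <- setNames(rep_len(c(deLog2FC, -deLog2FC), nDE), sel$deIds)

    specA <- do.call(librarySpec, c(specArgs, list(
        deEffects = effects, specificAbsent = sel$bSpecific,
        seed = seed + 2L)))
    specB <- do.call(librarySpec, c(specArgs, list(
        specificAbsent = sel$aSpecific, seed = seed + 3L)))

    libA <- simulateLibrary(ref$catalog, specA, ref$contaminants)
    libB <- simulateLibrary(ref$catalog, specB, ref$contaminants)

    mA <- libA$truth$matureCount; mB <- libB$truth$matureCount
    category <- ifelse(mA > 0 & mB > 0, "co-expressed",
                ifelse(mA > 0, "A-specific",
                ifelse(mB > 0, "B-specific", "undetected")))
    truth <- DataFrame(
        id = ids,
        matureA = mA, matureB = mB,
        starA = libA$truth$starCount, starB = libB$truth$starCount,
        log2Effect = libA$truth$log2Effect,
        isDE = ids %in% sel$deIds,
        specific = ifelse(ids %in% sel$aSpecific, "A",
                   ifelse(ids %in% sel$bSpecific, "B", "none")),
        category = category)
    list(catalog = ref$catalog, contaminants = ref$contaminants,
         specA = specA, specB = specB, libA = libA, libB = libB,
         truth = truth)
}

#' Write a simulated experiment to disk
#'
#' Materializes a [simulateExperiment()] result as the file set the
#' pipeline consumes: two FASTQ libraries, catalog FASTA + arm table,
#' one contaminant FASTA per class, and the truth table TSV.
#'
#' @param sim Result of [simulateExperiment()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths.
#' @export
writeSimulatedExperiment <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(
        fastqA = file.path(dir, "libA.fastq"),
        fastqB = file.path(dir, "libB.fastq"),
        catalogFasta = file.path(dir, "hairpins.fa"),
        armTable = file.path(dir, "arms.tsv"),
        truth = file.path(dir, "truth.tsv"))
    writeFastq(sim$libA$sequences, sim$libA$qualities, p$fastqA)
    writeFastq(sim$libB$sequences, sim$libB$qualities, p$fastqB)
    writeHairpinCatalog(sim$catalog, p$catalogFasta, p$armTable)
    p$contaminantFastas <- vapply(names(sim$contaminants), function(cls) {
        fp <- file.path(dir, paste0("contaminant_", cls, ".fa"))
        writeXStringSet(sim$contaminants[[cls]], fp)
        fp
    }, character(1))
    .writeTsv(sim$truth, p$truth)
    p
}
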