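#' Hairpin catalog of miRNA precursors with annotated arms
#'
#' A \code{HairpinCatalog} holds precursor (hairpin) sequences together with
#' the coordinates of their 5p and 3p arms and the annotation of which arm
#' is the mature miRNA; the opposite arm is the miRNA* (star). Arm
#' coordinates are 1-based closed intervals on the hairpin, stored as
#' \link[IRanges]{IRanges}.
#'
#' Validity requires: one arm pair per hairpin; each arm 20-24 nt; arms
#' disjoint with the 5p arm strictly before the 3p arm; both arms within
#' the hairpin; \code{matureArm} one of \code{"5p"}/\code{"3p"}; unique
#' hairpin ids.
#'
#' @slot hairpins A named \link[Biostrings]{DNAStringSet} of precursors
#'   (typically 60-80 nt).
#' @slot arm5p,arm3p \link[IRanges]{IRanges} of the arm positions.
#' @slot matureArm Character vector, \code{"5p"} or \code{"3p"} per hairpin.
#'
#' @seealso [generateCatalog()], [readHairpinCatalog()],
#'   [writeHairpinCatalog()]
#' @examples
#' cat <- generateCatalog(5, nContaminantsPerClass = 2, seed = 1)$catalog
#' cat
#' matureSeqs(cat)
#' @export
setClass("HairpinCatalog",
    slots = c(
        hairpins  = "DNAStringSet",
        arm5p     = "IRanges",
        arm3p     = "IRanges",
        matureArm = "character"
    )
)

setValidity("HairpinCatalog", function(object) {
    n <- length(object@hairpins)
    msg <- character(0)
    if (length(object@arm5p) != n || length(object@arm3p) != n ||
        length(object@matureArm) != n)
        msg <- c(msg, "hairpins, arm5p, arm3p and matureArm must be parallel")
    if (n > 0L && (is.null(names(object@hairpins)) ||
                   anyDuplicated(names(object@hairpins))))
        msg <- c(msg, "hairpins must have unique names")
    if (length(msg)) return(msg)
    if (n == 0L) return(TRUE)
    w5 <- width(object@arm5p); w3 <- width(object@arm3p)
    if (any(w5 < 20L | w5 > 24L) || any(w3 < 20L | w3 > 24L))
        msg <- c(msg, "arm widths must be 20-24 nt")
    if (any(start(object@arm5p) < 1L) ||
        any(end(object@arm3p) > width(object@hairpins)))
        msg <- c(msg, "arms must lie within their hairpin")
    if (any(end(object@arm5p) >= start(object@arm3p)))
        msg <- c(msg, "arm5p must precede and not overlap arm3p")
    if (!all(object@matureArm %in% c("5p", "3p")))
        msg <- c(msg, "matureArm must be '5p' or '3p'")
    if (length(msg)) msg else TRUE
})

#' Construct a HairpinCatalog
#'
#' @param hairpins Named \link[Biostrings]{DNAStringSet} (or named character
#'   vector) of precursor sequences.
#' @param arm5p,arm3p \link[IRanges]{IRanges} of arm coordinates (1-based,
#'   closed).
#' @param matureArm Character vector of \code{"5p"}/\code{"3p"}.
#' @return A [HairpinCatalog-class] object.
#' @export
HairpinCatalog <- function(hairpins, arm5p, arm3p, matureArm) {
    if (is.character(hairpins)) hairpins <- DNAStringSet(hairpins)
    new("HairpinCatalog", hairpins = hairpins, arm5p = arm5p,
        arm3p = arm3p, matureArm = matureArm)
}

#' Specification of one simulated small RNA library
#'
#' A \code{LibrarySpec} fixes every stochastic choice made when simulating a
#' raw read library from a [HairpinCatalog-class]: library size, per-miRNA
#' abundance law, planted differential-expression effects, library-specific
#' absences, the star-arm sampling rate, mixture fractions for contaminant,
#' unannotated and 5'-adapter-contaminant reads, the low-quality overlay,
#' the per-base substitution error rate, 3' length jitter, and the adapter
#' sequences. A fixed \code{seed} makes the simulated FASTQ byte-identical
#' across runs; \code{abundanceSeed} seeds only the per-miRNA baseline
#' abundances so that two libraries can share a baseline.
#'
#' @slot nReads Number of raw reads to emit.
#' @slot abundanceMu,abundanceSigma Log-normal meanlog/sdlog of per-miRNA
#'   expected counts (heavy-tailed abundances).
#' @slot abundanceSeed Integer seed for the baseline abundance draw.
#' @slot deEffects Named numeric: planted log2 effects applied to this
#'   library's abundances (id -> log2 fold effect).
#' @slot specificAbsent Character: miRNA ids forced to zero reads here.
#' @slot starFraction Probability a miRNA-derived read comes from the star
#'   arm.
#' @slot contaminantFraction,unannotatedFraction,adapter5Fraction Mixture
#'   probabilities of contaminant-ncRNA, random-sequence, and 5'-adapter
#'   contaminant reads.
#' @slot lowQualityFraction Fraction of reads overlaid with failing base
#'   qualities.
#' @slot errorRate Per-base substitution probability.
#' @slot jitterProb Numeric length-5 probabilities of 3' offsets -2..+2.
#' @slot adapter,adapter5 3' and 5' adapter sequences.
#' @slot seed Integer seed determining the library.
#'
#' @seealso [librarySpec()], [simulateLibrary()]
#' @export
setClass("LibrarySpec",
    slots = c(
        nReads = "integer",
        abundanceMu = "numeric", abundanceSigma = "numeric",
        abundanceSeed = "integer",
        deEffects = "numeric", specificAbsent = "character",
        starFraction = "numeric", contaminantFraction = "numeric",
        unannotatedFraction = "numeric", adapter5Fraction = "numeric",
        lowQualityFraction = "numeric",
        errorRate = "numeric", jitterProb = "numeric",
        adapter = "character", adapter5 = "character",
        seed = "integer"
    )
)

setValidity("LibrarySpec", function(object) {
    msg <- character(0)
    if (length(object@nReads) != 1L || is.na(object@nReads) ||
        object@nReads < 1L)
        msg <- c(msg, "nReads must be a positive integer")
    fr <- c(object@starFraction, object@contaminantFraction,
            object@unannotatedFraction, object@adapter5Fraction,
            object@lowQualityFraction, object@errorRate)
    if (any(fr < 0) || any(fr > 1))
        msg <- c(msg, "fractions and errorRate must lie in [0, 1]")
    if (object@contaminantFraction + object@unannotatedFraction +
        object@adapter5Fraction > 1)
        msg <- c(msg, "mixture fractions must sum to at most 1")
    if (length(object@jitterProb) != 5L || any(object@jitterProb < 0) ||
        abs(sum(object@jitterProb) - 1) > 1e-8)
        msg <- c(msg, "jitterProb must be 5 probabilities summing to 1")
    if (nchar(object@adapter) < 6L)
        msg <- c(msg, "adapter must be at least 6 nt (untrimmable otherwise)")
    if (length(object@deEffects) &&
        is.null(names(object@deEffects)))
        msg <- c(msg, "deEffects must be named by miRNA id")
    if (length(msg)) msg else TRUE
})

#' Create a library simulation specification
#'
#' See [LibrarySpec-class] for the meaning of each parameter. Defaults
#' describe a library dominated by 21-24 nt miRNA tags with a minority of
#' contaminant and unannotated reads, log-normal per-miRNA abundances, and
#' star arms sampled at a tenth of the mature rate.
#'
#' @param nReads Number of raw reads.
#' @param abundanceMu,abundanceSigma Log-normal meanlog/sdlog of per-miRNA
#'   abundance weights.
#' @param abundanceSeed Seed for the shared baseline abundance draw.
#' @param deEffects Named numeric of planted log2 effects.
#' @param specificAbsent miRNA ids emitting zero reads in this library.
#' @param starFraction,contaminantFraction,unannotatedFraction,adapter5Fraction
#'   Mixture probabilities (see [LibrarySpec-class]).
#' @param lowQualityFraction Fraction of reads with failing base qualities.
#' @param errorRate Per-base substitution probability.
#' @param jitterProb Probabilities for 3' offsets -2..+2.
#' @param adapter,adapter5 3' and 5' adapter sequences.
#' @param seed Integer seed; fully determines the library.
#' @return A [LibrarySpec-class] object.
#' @examples
#' spec <- librarySpec(1000, seed = 7)
#' spec
#' @export
librarySpec <- function(nReads,
                        abundanceMu = 0, abundanceSigma = 1.5,
                        abundanceSeed = 1L,
                        deEffects = numeric(0),
                        specificAbsent = character(0),
                        starFraction = 0.1,
                        contaminantFraction = 0.05,
                        unannotatedFraction = 0.10,
                        adapter5Fraction = 0.01,
                        lowQualityFraction = 0.02,
                        errorRate = 0.01,
                        jitterProb = c(0.05, 0.15, 0.6, 0.15, 0.05),
                        adapter = "TGGAATTCTCGGGTGCCAAGG",
                        adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                        seed = 1L) {
    new("LibrarySpec",
        nReads = as.integer(nReads),
        abundanceMu = abundanceMu, abundanceSigma = abundanceSigma,
        abundanceSeed = as.integer(abundanceSeed),
        deEffects = deEffects, specificAbsent = specificAbsent,
        starFraction = starFraction,
        contaminantFraction = contaminantFraction,
        unannotatedFraction = unannotatedFraction,
        adapter5Fraction = adapter5Fraction,
        lowQualityFraction = lowQualityFraction,
        errorRate = errorRate, jitterProb = jitterProb,
        adapter = toupper(adapter), adapter5 = toupper(adapter5),
        seed = as.integer(seed))
}

#' Read-cleaning accounting
#'
#' Per-library bookkeeping of the cleaning pipeline: every raw read is
#' either removed by exactly one filter or survives as a clean read, so
#' \code{cleanTotal = totalRaw - sum(removed*)}. \code{cleanTotal} is the
#' normalization denominator used for reads-per-million expression.
#'
#' @slot totalRaw,removedLowQuality,removedAdapter5,removedNoAdapter,removedLength,cleanTotal,uniqueCount
#'   Integer counts.
#' @seealso [cleanReads()]
#' @export
setClass("CleanStats",
    slots = c(
        totalRaw = "integer",
        removedLowQuality = "integer",
        removedAdapter5 = "integer",
        removedNoAdapter = "integer",
        removedLength = "integer",
        cleanTotal = "integer",
        uniqueCount = "integer"
    )
)

setValidity("CleanStats", function(object) {
    v <- c(object@totalRaw, object@removedLowQuality, object@removedAdapter5,
           object@removedNoAdapter, object@removedLength, object@cleanTotal,
           object@uniqueCount)
    if (any(v < 0L)) return("all counts must be non-negative")
    if (object@cleanTotal != object@totalRaw - object@removedLowQuality -
        object@removedAdapter5 - object@removedNoAdapter -
        object@removedLength)
        return("cleanTotal must equal totalRaw minus all removals")
    TRUE
})

#' Per-miRNA arm-level counts for two (or more) libraries
#'
#' A \code{MirnaCountSet} extends
#' \link[SummarizedExperiment]{SummarizedExperiment} with two integer
#' assays, \code{"mature"} and \code{"star"}, holding per-hairpin read
#' counts per library, and a required \code{cleanTotal} column in
#' \code{colData} giving each library's clean-read total (the
#' reads-per-million denominator). Rows are hairpin ids; columns are
#' libraries.
#'
#' @seealso [aggregateMirnaCounts()], [mirnaDiffExpr()], [findDuplexPairs()]
#' @export
setClass("MirnaCountSet", contains = "SummarizedExperiment")

setValidity("MirnaCountSet", function(object) {
    msg <- character(0)
    if (!all(c("mature", "star") %in% assayNames(object)))
        msg <- c(msg, "assays 'mature' and 'star' are required")
    else {
        if (any(assay(object, "mature") < 0) || any(assay(object, "star") < 0))
            msg <- c(msg, "counts must be non-negative")
    }
    if (!"cleanTotal" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain 'cleanTotal'")
    else if (any(colData(object)$cleanTotal <= 0))
        msg <- c(msg, "cleanTotal must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a MirnaCountSet
#'
#' @param mature,star Integer matrices (miRNA x library) of arm-level read
#'   counts, with identical dimnames.
#' @param cleanTotals Positive numeric vector of per-library clean-read
#'   totals, parallel to the columns.
#' @return A [MirnaCountSet-class].
#' @export
MirnaCountSet <- function(mature, star, cleanTotals) {
    se <- SummarizedExperiment(
        assays = list(mature = mature, star = star),
        colData = DataFrame(cleanTotal = unname(cleanTotals),
                            row.names = colnames(mature)))
    new("MirnaCountSet", se)
}
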