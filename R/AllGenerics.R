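#' Accessors for HairpinCatalog and MirnaCountSet
#'
#' \code{hairpins}, \code{arm5p}, \code{arm3p} and \code{matureArm} expose
#' the catalog slots; \code{matureSeqs}/\code{starSeqs} extract the mature
#' and star arm sequences; \code{matureCounts}/\code{starCounts} return the
#' count assays of a [MirnaCountSet-class]; \code{cleanTotals} returns the
#' per-library clean-read totals.
#'
#' @param x A [HairpinCatalog-class] or [MirnaCountSet-class].
#' @return The corresponding slot or derived object.
#' @name catalog-accessors
#' @examples
#' cat <- generateCatalog(3, nContaminantsPerClass = 2, seed = 1)$catalog
#' width(matureSeqs(cat))
NULL

#' @rdname catalog-accessors
#' @export
setGeneric("hairpins", function(x) standardGeneric("hairpins"))
#' @rdname catalog-accessors
#' @export
setGeneric("arm5p", function(x) standardGeneric("arm5p"))
#' @rdname catalog-accessors
#' @export
setGeneric("arm3p", function(x) standardGeneric("arm3p"))
#' @rdname catalog-accessors
#' @export
setGeneric("matureArm", function(x) standardGeneric("matureArm"))
#' @rdname catalog-accessors
#' @export
setGeneric("matureSeqs", function(x) standardGeneric("matureSeqs"))
#' @rdname catalog-accessors
#' @export
setGeneric("starSeqs", function(x) standardGeneric("starSeqs"))
#' @rdname catalog-accessors
#' @export
setGeneric("matureCounts", function(x) standardGeneric("matureCounts"))
#' @rdname catalog-accessors
#' @export
setGeneric("starCounts", function(x) standardGeneric("starCounts"))
#' @rdname catalog-accessors
#' @export
setGeneric("cleanTotals", function(x) standardGeneric("cleanTotals"))

#' @rdname catalog-accessors
#' @export
setMethod("hairpins", "HairpinCatalog", function(x) x@hairpins)
#' @rdname catalog-accessors
#' @export
setMethod("arm5p", "HairpinCatalog", function(x) x@arm5p)
#' @rdname catalog-accessors
#' @export
setMethod("arm3p", "HairpinCatalog", function(x) x@arm3p)
#' @rdname catalog-accessors
#' @export
setMethod("matureArm", "HairpinCatalog", function(x) x@matureArm)

#' @rdname catalog-accessors
#' @export
setMethod("length", "HairpinCatalog", function(x) length(x@hairpins))

#' @rdname catalog-accessors
#' @export
setMethod("names", "HairpinCatalog", function(x) names(x@hairpins))

.armSeqs <- function(x, which = c("mature", "star")) {
    which <- match.arg(which)
    use5p <- if (which == "mature") x@matureArm == "5p" else x@matureArm == "3p"
    ir <- x@arm3p
    ir[use5p] <- x@arm5p[use5p]
    out <- Biostrings::subseq(x@hairpins, start = start(ir), end = end(ir))
    names(out) <- names(x@hairpins)
    out
}

#' @rdname catalog-accessors
#' @export
setMethod("matureSeqs", "HairpinCatalog", function(x) .armSeqs(x, "mature"))
#' @rdname catalog-accessors
#' @export
setMethod("starSeqs", "HairpinCatalog", function(x) .armSeqs(x, "star"))

#' @rdname catalog-accessors
#' @export
setMethod("matureCounts", "MirnaCountSet", function(x) assay(x, "mature"))
#' @rdname catalog-accessors
#' @export
setMethod("starCounts", "MirnaCountSet", function(x) assay(x, "star"))
#' @rdname catalog-accessors
#' @export
setMethod("cleanTotals", "MirnaCountSet", function(x)
    setNames(colData(x)$cleanTotal, colnames(x)))

setMethod("show", "HairpinCatalog", function(object) {
    cat("HairpinCatalog with", length(object), "hairpins\n")
    if (length(object)) {
        cat("  hairpin widths:", min(width(object@hairpins)), "-",
            max(width(object@hairpins)), "nt\n")
        cat("  mature arm: ", sum(object@matureArm == "5p"), " x 5p, ",
            sum(object@matureArm == "3p"), " x 3p\n", sep = "")
    }
    invisible(object)
})

setMethod("show", "CleanStats", function(object) {
    cat("CleanStats\n")
    cat("  total raw reads:      ", object@totalRaw, "\n")
    cat("  removed low-quality:  ", object@removedLowQuality, "\n")
    cat("  removed 5' adapter:   ", object@removedAdapter5, "\n")
    cat("  removed no 3' adapter:", object@removedNoAdapter, "\n")
    cat("  removed by length:    ", object@removedLength, "\n")
    cat("  clean reads:          ", object@cleanTotal, "\n")
    cat("  unique tags:          ", object@uniqueCount, "\n")
    invisible(object)
})

setMethod("show", "LibrarySpec", function(object) {
    cat("LibrarySpec:", object@nReads, "reads, seed", object@seed, "\n")
    cat(sprintf("  mixture: %.3f contaminant, %.3f unannotated, %.3f 5'-contaminant\n",
        object@contaminantFraction, object@unannotatedFraction,
        object@adapter5Fraction))
    cat(sprintf("  star fraction %.3f, error rate %.4f, low-quality %.3f\n",
        object@starFraction, object@errorRate, object@lowQualityFraction))
    if (length(object@deEffects))
        cat("  planted effects on", length(object@deEffects), "miRNAs\n")
    if (length(object@specificAbsent))
        cat("  absent miRNAs:", length(object@specificAbsent), "\n")
    invisible(object)
})

setMethod("show", "MirnaCountSet", function(object) {
    cat("MirnaCountSet:", nrow(object), "miRNAs x", ncol(object),
        "libraries\n")
    cat("  libraries:", paste(colnames(object), collapse = ", "), "\n")
    cat("  clean totals:", paste(colData(object)$cleanTotal, collapse = ", "),
        "\n")
    cat("  mature reads:", paste(colSums(assay(object, "mature")),
        collapse = ", "), "\n")
    cat("  star reads:  ", paste(colSums(assay(object, "star")),
        collapse = ", "), "\n")
    invisible(object)
})

#' Clean-read total of a CleanStats record
#' @param x A [CleanStats-class] object.
#' @return Integer clean-read total.
#' @export
setMethod("cleanTotals", "CleanStats", function(x) x@cleanTotal)
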