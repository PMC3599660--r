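# Raw reads -> clean reads -> collapsed unique tags, with full accounting.

#' Trim the 3' adapter from a read
#'
#' Scans every start position for the best adapter match, allowing the
#' adapter to run off the read end (suffix overlap). Scoring maximizes the
#' aligned overlap, then minimizes mismatches, then prefers the leftmost
#' position; a candidate is acceptable when the overlap spans at least
#' \code{minOverlap} bases and carries at most
#' \code{floor(maxMismatchRate * overlap)} substitutions.
#'
#' @param read Read sequence (character scalar or vector).
#' @param adapter 3' adapter sequence (>= \code{minOverlap} nt).
#' @param minOverlap Minimum aligned adapter bases.
#' @param maxMismatchRate Maximum mismatch fraction over the aligned span.
#' @return The insert (read prefix before the adapter), or
#'   \code{NA_character_} when no acceptable adapter match exists.
#'   Vectorized over \code{read}.
#' @examples
#' trimAdapter("ACGTACGTTGGAATTC", "TGGAATTC")     # "ACGTACGT"
#' trimAdapter("ACGTACGT", "TGGAATTC")             # NA: adapter absent
#' @export
trimAdapter <- function(read, adapter, minOverlap = 6L,
                        maxMismatchRate = 0.1) {
    if (nchar(adapter) < minOverlap)
        stop("adapter must be at least minOverlap bases long")
    pos <- trim_adapter_pos(toupper(read), toupper(adapter),
                            as.integer(minOverlap), maxMismatchRate)
    out <- substr(read, 1L, pos)       # pos is 0-based insert length
    out[pos < 0L] <- NA_character_
    out
}

#' Clean a raw read library
#'
#' Applies the fixed filter cascade: (1) whole-read quality filter (a read
#' fails when more than \code{maxLowQualFrac} of its bases are below Phred
#' \code{qualityThreshold}, or it contains more than \code{maxN} N bases);
#' (2) removal of 5'-adapter contaminants (reads whose 5' end matches the
#' first \code{adapter5Overlap} bases of the 5' adapter with at most one
#' mismatch); (3) 3' adapter trimming (reads without an acceptable adapter
#' match are discarded); (4) insert length filter
#' \code{[minLen, maxLen]} -- reads trimmed to an empty or too-short
#' insert, including pure-adapter reads, are removed here.
#'
#' @param fastq Path to a FASTQ file, or a list with \code{sequences} and
#'   \code{qualities} as returned by [readFastq()]/[simulateLibrary()].
#' @param adapter 3' adapter sequence.
#' @param adapter5 5' adapter sequence (used only to flag contaminants).
#' @param qualityThreshold Phred floor for a "good" base.
#' @param maxLowQualFrac Maximum tolerated fraction of low-quality bases.
#' @param maxN Maximum tolerated N bases.
#' @param minLen,maxLen Post-trim insert length window.
#' @param minOverlap,maxMismatchRate Adapter-match parameters, see
#'   [trimAdapter()].
#' @param adapter5Overlap 5' bases compared for contaminant flagging.
#' @return A list with \code{reads} (character vector of clean inserts)
#'   and \code{stats} (a [CleanStats-class]).
#' @export
cleanReads <- function(fastq, adapter,
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       qualityThreshold = 20L, maxLowQualFrac = 0.2,
                       maxN = 2L, minLen = 15L, maxLen = 35L,
                       minOverlap = 6L, maxMismatchRate = 0.1,
                       adapter5Overlap = 10L) {
    if (is.character(fastq)) fastq <- readFastq(fastq)
    seqs <- toupper(fastq$sequences)
    quals <- fastq$qualities
    total <- length(seqs)

    # per-base Phred scores without a per-read loop
    lens <- nchar(seqs)
    grp <- rep.int(seq_along(seqs), lens)
    phred <- as.integer(charToRaw(paste(quals, collapse = ""))) - 33L
    lowFrac <- as.vector(rowsum(as.integer(phred < qualityThreshold), grp)) /
        pmax(lens, 1L)
    nN <- as.vector(rowsum(
        as.integer(charToRaw(paste(seqs, collapse = "")) == as.raw(78L)),
        grp))
    lowQual <- lowFrac > maxLowQualFrac | nN > maxN

    keep <- !lowQual
    # 5' adapter contaminants
    ov <- min(adapter5Overlap, nchar(adapter5))
    a5 <- strsplit(toupper(substr(adapter5, 1L, ov)), "")[[1]]
    mism5 <- integer(total)
    for (j in seq_len(ov))
        mism5 <- mism5 + (substr(seqs, j, j) != a5[j])
    isAd5 <- keep & lens >= ov & mism5 <= 1L
    keep <- keep & !isAd5

    # 3' adapter trim
    ins <- rep(NA_character_, total)
    ins[keep] <- trimAdapter(seqs[keep], adapter, minOverlap,
                             maxMismatchRate)
    noAd <- keep & is.na(ins)
    keep <- keep & !noAd

    inLen <- nchar(ins)
    badLen <- keep & (inLen < minLen | inLen > maxLen)
    keep <- keep & !badLen

    clean <- ins[keep]
    stats <- new("CleanStats",
        totalRaw = total,
        removedLowQuality = sum(lowQual),
        removedAdapter5 = sum(isAd5),
        removedNoAdapter = sum(noAd),
        removedLength = sum(badLen),
        cleanTotal = length(clean),
        uniqueCount = length(unique(clean)))
    list(reads = clean, stats = stats)
}

#' Collapse identical reads into unique tags
#'
#' Groups exact-identical sequences, preserving total read count. The
#' result is sorted by descending count, ties broken lexicographically.
#'
#' @param reads Character vector of clean read sequences.
#' @return A \code{DataFrame} with columns \code{seq} and \code{count}.
#' @examples
#' collapseReads(c("AAA", "AAA", "CCC"))
#' @export
collapseReads <- function(reads) {
    if (length(reads) == 0L)
        return(DataFrame(seq = character(0), count = integer(0)))
    r <- rle(sort(reads))
    o <- order(-r$lengths, r$values)
    DataFrame(seq = r$values[o], count = r$lengths[o])
}

#' Read-length frequency distribution
#'
#' @param reads Non-empty character vector of clean reads.
#' @return Named numeric vector mapping length to the fraction of reads;
#'   fractions sum to 1.
#' @examples
#' lengthDistribution(c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
#'                      "ACGTACGTACGTACGTACGTACGT"))
#' @export
lengthDistribution <- function(reads) {
    if (length(reads) == 0L) stop("empty read list")
    tab <- table(nchar(reads))
    out <- as.numeric(tab) / length(reads)
    names(out) <- names(tab)
    out
}
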