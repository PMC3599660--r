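# Tag classification by RNA class, mismatch-tolerant miRNA assignment,
# arm-level count aggregation, duplex detection, composition summary.

.CONTAM_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")
.RNA_CLASSES <- c(.CONTAM_CLASSES, "miRNA", "miRNA_star", "unannotated")

.dnaUp <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Match a tag against a reference sequence with substitutions and shifts
#'
#' Considers ungapped alignments of the tag against the reference at start
#' offsets in \code{[-maxShift, +maxShift]} (offset = tag start minus
#' reference start; no indels). A hit requires an overlap of at least
#' \code{min(nchar(tag), nchar(ref)) - maxShift} bases with at most
#' \code{maxSub} mismatches on the overlap. Among hits the one with the
#' fewest mismatches wins, then the smallest \code{|offset|}, then the
#' negative offset. U is treated as T.
#'
#' @param tagSeq,refSeq Sequences over A/C/G/T/U.
#' @param maxSub Maximum substitutions (default 2, the conserved-miRNA
#'   tolerance).
#' @param maxShift Maximum start offset (default 2, accommodating
#'   isomiR-like end variation).
#' @return A list with \code{nMismatches} and \code{offset}, or
#'   \code{NULL} when there is no acceptable alignment.
#' @examples
#' matchTag("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA")  # 0 mism
#' @export
matchTag <- function(tagSeq, refSeq, maxSub = 2L, maxShift = 2L) {
    if (!nzchar(tagSeq) || !nzchar(refSeq))
        stop("empty sequence")
    hit <- match_tags_best(.dnaUp(tagSeq), .dnaUp(refSeq),
                           as.integer(maxSub), as.integer(maxShift))
    if (hit[1, 1] == 0L) return(NULL)
    list(nMismatches = hit[1, 2], offset = hit[1, 3])
}

#' Classify unique tags into RNA classes by priority
#'
#' Each tag receives the first class, in priority order, in which it has a
#' hit. Contaminant classes (checked first) require the whole tag to align
#' inside a reference with at most \code{contamMaxMismatch} substitutions.
#' Tags surviving all contaminant classes and whose length falls within
#' \code{mirnaLenRange} are matched against the catalog's mature and star
#' arms with [matchTag()] semantics; a hit on the annotated mature arm is
#' classed \code{miRNA}, a hit on the opposite arm \code{miRNA_star}
#' (identity comes from the catalog annotation, not relative abundance).
#' Ties between hairpins go to the earlier catalog entry. Everything else
#' is \code{unannotated}. Tags are classified independently, so the result
#' does not depend on input order.
#'
#' @param tags \code{DataFrame} with columns \code{seq}, \code{count}
#'   ([collapseReads()] output).
#' @param catalog A [HairpinCatalog-class].
#' @param contaminants Named list of \link[Biostrings]{DNAStringSet}, one
#'   per contaminant class.
#' @param priority Character vector ordering the contaminant classes;
#'   must name entries of \code{contaminants} (unknown names are a
#'   configuration error). miRNA matching always follows the contaminant
#'   classes.
#' @param maxSub,maxShift miRNA matching parameters, see [matchTag()].
#' @param contamMaxMismatch Mismatch tolerance of the containment match.
#' @param mirnaLenRange Tag length window eligible for a miRNA call.
#' @return A \code{DataFrame} with columns \code{seq}, \code{count},
#'   \code{rnaClass}, \code{assignedId}, \code{nMismatches},
#'   \code{offset}.
#' @export
classifyTags <- function(tags, catalog, contaminants = list(),
                         priority = names(contaminants),
                         maxSub = 2L, maxShift = 2L,
                         contamMaxMismatch = 1L,
                         mirnaLenRange = c(18L, 26L)) {
    if (length(priority) && !all(priority %in% names(contaminants)))
        stop("unknown class name in priority: ",
             paste(setdiff(priority, names(contaminants)), collapse = ", "))
    n <- nrow(tags)
    cls <- rep("unannotated", n)
    aid <- rep(NA_character_, n)
    nmm <- rep(NA_integer_, n)
    off <- rep(NA_integer_, n)
    seqs <- .dnaUp(tags$seq)
    open <- rep(TRUE, n)

    for (p in priority) {
        idx <- which(open)
        if (!length(idx)) break
        refs <- .dnaUp(as.character(contaminants[[p]]))
        hit <- contain_match_best(seqs[idx], refs,
                                  as.integer(contamMaxMismatch))
        got <- hit[, 1] > 0L
        cls[idx[got]] <- p
        aid[idx[got]] <- names(contaminants[[p]])[hit[got, 1]]
        nmm[idx[got]] <- hit[got, 2]
        open[idx[got]] <- FALSE
    }

    idx <- which(open & nchar(seqs) >= mirnaLenRange[1] &
                 nchar(seqs) <= mirnaLenRange[2])
    if (length(idx) && length(catalog)) {
        mat <- .dnaUp(as.character(matureSeqs(catalog)))
        st <- .dnaUp(as.character(starSeqs(catalog)))
        # interleave mature/star so earlier hairpins win ties
        refs <- as.vector(rbind(mat, st))
        hit <- match_tags_best(seqs[idx], refs,
                               as.integer(maxSub), as.integer(maxShift))
        got <- hit[, 1] > 0L
        hp <- (hit[got, 1] + 1L) %/% 2L        # hairpin index
        isStar <- hit[got, 1] %% 2L == 0L
        cls[idx[got]] <- ifelse(isStar, "miRNA_star", "miRNA")
        aid[idx[got]] <- names(catalog)[hp]
        nmm[idx[got]] <- hit[got, 2]
        off[idx[got]] <- hit[got, 3]
    }

    lev <- unique(c(priority, "miRNA", "miRNA_star", "unannotated"))
    DataFrame(seq = tags$seq, count = tags$count,
              rnaClass = factor(cls, levels = lev),
              assignedId = aid, nMismatches = nmm, offset = off)
}

#' Aggregate tag annotations into per-miRNA arm counts
#'
#' Sums tag counts per hairpin and arm for each library. Hairpins with
#' zero counts on both arms in every library are omitted.
#'
#' @param annotations Named list of [classifyTags()] outputs, one per
#'   library (the names become library names).
#' @param cleanTotals Numeric vector of clean-read totals, parallel to
#'   \code{annotations}.
#' @return A [MirnaCountSet-class].
#' @export
aggregateMirnaCounts <- function(annotations, cleanTotals) {
    stopifnot(length(annotations) == length(cleanTotals))
    libs <- names(annotations)
    if (is.null(libs)) libs <- paste0("lib", seq_along(annotations))
    ids <- sort(unique(unlist(lapply(annotations, function(a)
        a$assignedId[a$rnaClass %in% c("miRNA", "miRNA_star")]))))
    mature <- star <- matrix(0L, nrow = length(ids), ncol = length(libs),
                             dimnames = list(ids, libs))
    for (j in seq_along(annotations)) {
        a <- annotations[[j]]
        for (arm in c("miRNA", "miRNA_star")) {
            sel <- a$rnaClass == arm
            if (!any(sel)) next
            s <- rowsum(a$count[sel], a$assignedId[sel])
            tgt <- match(rownames(s), ids)
            if (arm == "miRNA") mature[tgt, j] <- as.integer(s)
            else star[tgt, j] <- as.integer(s)
        }
    }
    MirnaCountSet(mature, star, cleanTotals)
}

#' Find miRNA:miRNA* duplex-like pairs
#'
#' A hairpin is reported for a library when both its mature and its star
#' arm are detected there with at least \code{minCount} reads.
#'
#' @param x A [MirnaCountSet-class].
#' @param minCount Minimum reads per arm.
#' @return A \code{DataFrame} with columns \code{id}, \code{library},
#'   \code{matureCount}, \code{starCount}, one row per detected pair.
#' @export
findDuplexPairs <- function(x, minCount = 1L) {
    stopifnot(is(x, "MirnaCountSet"))
    m <- matureCounts(x); s <- starCounts(x)
    res <- lapply(colnames(x), function(lib) {
        sel <- m[, lib] >= minCount & s[, lib] >= minCount
        DataFrame(id = rownames(x)[sel],
                  library = rep(lib, sum(sel)),
                  matureCount = m[sel, lib],
                  starCount = s[sel, lib])
    })
    do.call(rbind, res)
}

#' Composition of a library by RNA class
#'
#' Per-class totals and fractions of reads and of unique tags. Rows cover
#' the base classes (each tag in exactly one); an extra \code{miRNA_all}
#' row merges \code{miRNA} and \code{miRNA_star} and is excluded from the
#' sum-to-one guarantee (flagged by \code{merged}).
#'
#' @param annotation A [classifyTags()] output.
#' @return A \code{DataFrame} with columns \code{class}, \code{reads},
#'   \code{readFraction}, \code{uniqueTags}, \code{uniqueFraction},
#'   \code{merged}.
#' @export
compositionSummary <- function(annotation) {
    if (nrow(annotation) == 0L) stop("empty annotation")
    totReads <- sum(annotation$count)
    totTags <- nrow(annotation)
    reads <- as.vector(tapply(annotation$count, annotation$rnaClass, sum,
                              default = 0))
    tagsN <- as.vector(table(annotation$rnaClass))
    out <- DataFrame(
        class = levels(annotation$rnaClass),
        reads = reads,
        readFraction = reads / totReads,
        uniqueTags = tagsN,
        uniqueFraction = tagsN / totTags,
        merged = FALSE)
    mir <- out$class %in% c("miRNA", "miRNA_star")
    merged <- DataFrame(
        class = "miRNA_all",
        reads = sum(out$reads[mir]),
        readFraction = sum(out$readFraction[mir]),
        uniqueTags = sum(out$uniqueTags[mir]),
        uniqueFraction = sum(out$uniqueFraction[mir]),
        merged = TRUE)
    rbind(out, merged)
}
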