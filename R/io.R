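# File input/output: FASTQ, catalog FASTA + arm table, collapsed FASTA.

#' Read a FASTQ file
#'
#' Thin wrapper around \link[Biostrings]{readDNAStringSet} that returns the
#' plain sequences and quality strings. On a malformed file the error names
#' the first offending record index.
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A list with character vectors \code{sequences}, \code{qualities}
#'   and \code{ids}.
#' @export
readFastq <- function(path) {
    res <- tryCatch({
        x <- readDNAStringSet(path, format = "fastq",
                              with.qualities = TRUE)
        list(sequences = as.character(x),
             qualities = as.character(mcols(x)$qualities),
             ids = names(x))
    }, error = function(e) e)
    if (inherits(res, "error")) {
        idx <- .locateBadFastqRecord(path)
        stop("malformed FASTQ record at index ", idx, ": ",
             conditionMessage(res))
    }
    res
}

# best-effort scan for the first structurally broken 4-line record
.locateBadFastqRecord <- function(path) {
    lines <- tryCatch(readLines(path, warn = FALSE),
                      error = function(e) character(0))
    n <- length(lines)
    nrec <- n %/% 4L
    for (i in seq_len(nrec)) {
        b <- (i - 1L) * 4L
        if (!startsWith(lines[b + 1L], "@") ||
            !startsWith(lines[b + 3L], "+") ||
            nchar(lines[b + 2L]) != nchar(lines[b + 4L]))
            return(i)
    }
    if (n %% 4L != 0L) return(nrec + 1L)
    NA_integer_
}

#' Write reads to FASTQ (Sanger quality encoding)
#'
#' @param sequences,qualities Parallel character vectors.
#' @param path Output path.
#' @param ids Optional read names; defaults to \code{read1..readN}.
#' @return The path, invisibly.
#' @export
writeFastq <- function(sequences, qualities, path, ids = NULL) {
    stopifnot(length(sequences) == length(qualities))
    if (is.null(ids)) ids <- paste0("read", seq_along(sequences))
    dss <- DNAStringSet(sequences)
    names(dss) <- ids
    writeXStringSet(dss, path, format = "fastq",
                    qualities = BStringSet(qualities))
    invisible(path)
}

#' Read and write a hairpin catalog
#'
#' The on-disk form is a FASTA of precursor sequences plus a tab-separated
#' arm-coordinate table with columns \code{id}, \code{arm5p_start},
#' \code{arm5p_end}, \code{arm3p_start}, \code{arm3p_end},
#' \code{mature_arm}, using 0-based half-open coordinates. In memory,
#' coordinates are 1-based closed [IRanges].
#'
#' @param fastaPath Path to the precursor FASTA.
#' @param armPath Path to the arm-coordinate TSV.
#' @return \code{readHairpinCatalog}: a [HairpinCatalog-class].
#' @export
readHairpinCatalog <- function(fastaPath, armPath) {
    seqs <- readDNAStringSet(fastaPath)
    arms <- read.delim(armPath, stringsAsFactors = FALSE)
    need <- c("id", "arm5p_start", "arm5p_end", "arm3p_start",
              "arm3p_end", "mature_arm")
    if (!all(need %in% colnames(arms)))
        stop("arm table must have columns: ", paste(need, collapse = ", "))
    m <- match(names(seqs), arms$id)
    if (anyNA(m))
        stop("arm table is missing hairpins: ",
             paste(names(seqs)[is.na(m)], collapse = ", "))
    arms <- arms[m, ]
    HairpinCatalog(
        hairpins = seqs,
        arm5p = IRanges(arms$arm5p_start + 1L, arms$arm5p_end),
        arm3p = IRanges(arms$arm3p_start + 1L, arms$arm3p_end),
        matureArm = arms$mature_arm)
}

#' @rdname readHairpinCatalog
#' @param catalog A [HairpinCatalog-class].
#' @export
writeHairpinCatalog <- function(catalog, fastaPath, armPath) {
    writeXStringSet(hairpins(catalog), fastaPath)
    tab <- data.frame(
        id = names(catalog),
        arm5p_start = start(arm5p(catalog)) - 1L,
        arm5p_end = end(arm5p(catalog)),
        arm3p_start = start(arm3p(catalog)) - 1L,
        arm3p_end = end(arm3p(catalog)),
        mature_arm = matureArm(catalog))
    write.table(tab, armPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(fastaPath, armPath))
}

#' Write collapsed unique tags as FASTA
#'
#' Headers follow the common collapsed-FASTA dialect
#' \code{tag<rank>_x<count>}.
#'
#' @param tags A \code{DataFrame} with columns \code{seq} and \code{count}
#'   as returned by [collapseReads()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCollapsedFasta <- function(tags, path) {
    dss <- DNAStringSet(tags$seq)
    names(dss) <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$count)
    writeXStringSet(dss, path)
    invisible(path)
}

#' Read a collapsed-tag FASTA back into a tag table
#'
#' @param path Path to a FASTA written by [writeCollapsedFasta()].
#' @return A \code{DataFrame} with columns \code{seq}, \code{count}.
#' @export
readCollapsedFasta <- function(path) {
    dss <- readDNAStringSet(path)
    counts <- suppressWarnings(
        as.integer(sub(".*_x(\\d+)$", "\\1", names(dss))))
    if (anyNA(counts))
        stop("headers must follow the tag<rank>_x<count> convention")
    DataFrame(seq = unname(as.character(dss)), count = counts)
}

# write a DataFrame/data.frame as TSV
.writeTsv <- function(x, path) {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
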