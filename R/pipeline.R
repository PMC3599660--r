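# End-to-end orchestration: config validation, staged execution
# (preprocess -> annotate -> diffexpr), TSV artifacts, summary report.

#' Build and validate a pipeline configuration
#'
#' All referenced files are checked at construction time, so a broken
#' configuration fails before any computation. Configurations are plain
#' lists; [readPipelineConfig()] loads one from a YAML file with the same
#' keys.
#'
#' @param fastqA,fastqB Paths to the two raw FASTQ libraries (A =
#'   treatment, B = control).
#' @param catalogFasta,armTable Hairpin catalog files
#'   ([readHairpinCatalog()]).
#' @param contaminantFastas Named character vector or list mapping
#'   contaminant class to FASTA path (may be empty).
#' @param adapter,adapter5 3' and 5' adapter sequences.
#' @param qualityThreshold,maxLowQualFrac,maxN,minLen,maxLen,minOverlap,maxMismatchRate
#'   Cleaning parameters, see [cleanReads()].
#' @param priority Contaminant class priority order, see [classifyTags()].
#' @param maxSub,maxShift,mirnaLenRange miRNA matching parameters.
#' @param sided Tail convention of the exact test.
#' @param floor Expression inclusion floor (RPM).
#' @param outDir Output directory for the run artifacts.
#' @param seed Integer seed recorded with the run (the analysis itself is
#'   deterministic).
#' @return A validated configuration list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(fastqA, fastqB, catalogFasta, armTable,
                           contaminantFastas = character(0),
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                           qualityThreshold = 20L, maxLowQualFrac = 0.2,
                           maxN = 2L, minLen = 15L, maxLen = 35L,
                           minOverlap = 6L, maxMismatchRate = 0.1,
                           priority = NULL, maxSub = 2L, maxShift = 2L,
                           mirnaLenRange = c(18L, 26L),
                           sided = "two_sided_min_doubled", floor = 1,
                           outDir = tempfile("miRPair_run"), seed = 1L) {
    cfg <- list(fastqA = fastqA, fastqB = fastqB,
                catalogFasta = catalogFasta, armTable = armTable,
                contaminantFastas = unlist(contaminantFastas),
                adapter = adapter, adapter5 = adapter5,
                qualityThreshold = qualityThreshold,
                maxLowQualFrac = maxLowQualFrac, maxN = maxN,
                minLen = minLen, maxLen = maxLen,
                minOverlap = minOverlap,
                maxMismatchRate = maxMismatchRate,
                priority = priority, maxSub = maxSub,
                maxShift = maxShift, mirnaLenRange = mirnaLenRange,
                sided = sided, floor = floor, outDir = outDir,
                seed = as.integer(seed))
    files <- c(cfg$fastqA, cfg$fastqB, cfg$catalogFasta, cfg$armTable,
               cfg$contaminantFastas)
    missing <- files[!file.exists(files)]
    if (length(missing))
        stop("configuration references missing files: ",
             paste(missing, collapse = ", "))
    if (cfg$minLen > cfg$maxLen) stop("minLen must not exceed maxLen")
    if (cfg$floor < 0) stop("floor must be non-negative")
    class(cfg) <- "pipelineConfig"
    cfg
}

#' @rdname pipelineConfig
#' @param path Path to a YAML configuration file whose keys mirror the
#'   arguments of \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(pipelineConfig, y)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full two-library analysis pipeline
#'
#' Executes preprocess -> annotate -> diffexpr on both libraries, writes
#' every stage table to \code{config$outDir} (clean stats, length
#' distributions, tag annotations, composition, arm-level counts, duplex
#' pairs, expression records, summary report), and returns the in-memory
#' results. The run is deterministic: the same configuration always
#' produces bit-identical artifacts.
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, a list with \code{cleanA}, \code{cleanB} (reads +
#'   [CleanStats-class]), \code{annotA}, \code{annotB}, \code{counts}
#'   (a [MirnaCountSet-class]), \code{duplex}, \code{results}
#'   (the [mirnaDiffExpr()] table), \code{summary}
#'   ([categorySummary()]), and \code{outDir}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

    catalog <- .stage("load-references",
        readHairpinCatalog(config$catalogFasta, config$armTable))
    contaminants <- .stage("load-references", {
        out <- lapply(config$contaminantFastas, readDNAStringSet)
        names(out) <- names(config$contaminantFastas)
        out
    })
    priority <- config$priority
    if (is.null(priority)) priority <- names(contaminants)

    doLib <- function(fq, lab) {
        cl <- .stage(paste0("preprocess-", lab), cleanReads(
            fq, adapter = config$adapter, adapter5 = config$adapter5,
            qualityThreshold = config$qualityThreshold,
            maxLowQualFrac = config$maxLowQualFrac, maxN = config$maxN,
            minLen = config$minLen, maxLen = config$maxLen,
            minOverlap = config$minOverlap,
            maxMismatchRate = config$maxMismatchRate))
        tags <- collapseReads(cl$reads)
        an <- .stage(paste0("annotate-", lab), classifyTags(
            tags, catalog, contaminants, priority = priority,
            maxSub = config$maxSub, maxShift = config$maxShift,
            mirnaLenRange = config$mirnaLenRange))
        list(clean = cl, tags = tags, annot = an)
    }
    A <- doLib(config$fastqA, "A")
    B <- doLib(config$fastqB, "B")

    counts <- .stage("annotate-aggregate", aggregateMirnaCounts(
        list(A = A$annot, B = B$annot),
        c(A$clean$stats@cleanTotal, B$clean$stats@cleanTotal)))
    duplex <- findDuplexPairs(counts)
    results <- .stage("diffexpr", mirnaDiffExpr(
        counts, treatment = "A", control = "B", floor = config$floor,
        sided = config$sided))
    summary <- categorySummary(results)

    od <- config$outDir
    statsTab <- data.frame(
        library = c("A", "B"),
        totalRaw = c(A$clean$stats@totalRaw, B$clean$stats@totalRaw),
        removedLowQuality = c(A$clean$stats@removedLowQuality,
                              B$clean$stats@removedLowQuality),
        removedAdapter5 = c(A$clean$stats@removedAdapter5,
                            B$clean$stats@removedAdapter5),
        removedNoAdapter = c(A$clean$stats@removedNoAdapter,
                             B$clean$stats@removedNoAdapter),
        removedLength = c(A$clean$stats@removedLength,
                          B$clean$stats@removedLength),
        cleanTotal = c(A$clean$stats@cleanTotal,
                       B$clean$stats@cleanTotal),
        uniqueCount = c(A$clean$stats@uniqueCount,
                        B$clean$stats@uniqueCount))
    .writeTsv(statsTab, file.path(od, "clean_stats.tsv"))
    for (lab in c("A", "B")) {
        lib <- if (lab == "A") A else B
        ld <- lengthDistribution(lib$clean$reads)
        .writeTsv(data.frame(length = as.integer(names(ld)),
                             fraction = as.numeric(ld)),
                  file.path(od, paste0("length_distribution_", lab,
                                       ".tsv")))
        .writeTsv(lib$annot,
                  file.path(od, paste0("tag_annotation_", lab, ".tsv")))
        .writeTsv(compositionSummary(lib$annot),
                  file.path(od, paste0("composition_", lab, ".tsv")))
    }
    countTab <- data.frame(id = rownames(counts),
                           matureA = matureCounts(counts)[, "A"],
                           matureB = matureCounts(counts)[, "B"],
                           starA = starCounts(counts)[, "A"],
                           starB = starCounts(counts)[, "B"])
    .writeTsv(countTab, file.path(od, "mirna_counts.tsv"))
    .writeTsv(duplex, file.path(od, "duplex_pairs.tsv"))
    .writeTsv(results, file.path(od, "expression_records.tsv"))
    writeLines(.reportLines(results, summary, statsTab, duplex),
               file.path(od, "summary.txt"))

    invisible(list(cleanA = A$clean, cleanB = B$clean,
                   annotA = A$annot, annotB = B$annot,
                   counts = counts, duplex = duplex, results = results,
                   summary = summary, outDir = od))
}

.reportLines <- function(results, summary, statsTab, duplex) {
    fmtTop <- function(lib) {
        top <- topExpressed(results, lib, 10L)
        if (nrow(top) == 0L) return("  (no miRNAs)")
        sprintf("  %-16s NE_A %12.2f  NE_B %12.2f  fc %7.2f %s",
                top$id, top$neA, top$neB, top$foldChange, top$sigLabel)
    }
    pc <- function(k) if (summary$nTotal > 0)
        sprintf("%d (%.2f%%)", k, percentOf(k, summary$nTotal))
        else "0"
    c("miRPair run summary",
      "===================",
      "",
      sprintf("Clean reads: A = %d, B = %d",
              statsTab$cleanTotal[1], statsTab$cleanTotal[2]),
      sprintf("Unique tags: A = %d, B = %d",
              statsTab$uniqueCount[1], statsTab$uniqueCount[2]),
      "",
      sprintf("Unique miRNA entities: %d", summary$nTotal),
      sprintf("  co-expressed: %s", pc(summary$nCoexpressed)),
      sprintf("  A-specific:   %s", pc(summary$nASpecific)),
      sprintf("  B-specific:   %s", pc(summary$nBSpecific)),
      sprintf("Significantly differentially expressed: %s",
              pc(summary$nSignificant)),
      sprintf("  upregulated in A:   %d (%d A-specific, %d co-expressed)",
              summary$nUp, summary$nUpASpecific, summary$nUpCoexpressed),
      sprintf("  downregulated in A: %d (%d B-specific, %d co-expressed)",
              summary$nDown, summary$nDownBSpecific,
              summary$nDownCoexpressed),
      "",
      sprintf("Duplex-like miRNA:miRNA* pairs: A = %d, B = %d",
              sum(duplex$library == "A"), sum(duplex$library == "B")),
      "",
      "Top 10 by expression in library A:", fmtTop("A"),
      "",
      "Top 10 by expression in library B:", fmtTop("B"))
}

#' Regenerate the human-readable summary from a completed run
#'
#' Accepts either the list returned by [runPipeline()] or the path of a
#' run directory; in the latter case the stage TSVs are re-read, and a
#' missing artifact is an error naming what is absent. Every reported
#' number is recomputed from the stage tables (only [percentOf()] and
#' sorting are applied on top).
#'
#' @param run A [runPipeline()] result or a run directory path.
#' @return Character vector of report lines (also printed).
#' @export
makeReport <- function(run) {
    if (is.character(run)) {
        need <- c("expression_records.tsv", "clean_stats.tsv",
                  "duplex_pairs.tsv")
        missing <- need[!file.exists(file.path(run, need))]
        if (length(missing))
            stop("incomplete run directory; missing: ",
                 paste(missing, collapse = ", "))
        results <- DataFrame(read.delim(
            file.path(run, "expression_records.tsv")))
        statsTab <- read.delim(file.path(run, "clean_stats.tsv"))
        duplex <- DataFrame(read.delim(file.path(run,
                                                 "duplex_pairs.tsv")))
        lines <- .reportLines(results, categorySummary(results),
                              statsTab, duplex)
    } else {
        lines <- .reportLines(run$results, run$summary,
                              read.delim(file.path(run$outDir,
                                                   "clean_stats.tsv")),
                              run$duplex)
    }
    cat(lines, sep = "\n")
    invisible(lines)
}
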