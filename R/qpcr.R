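# qPCR validation arithmetic: U6-normalized relative expression, group
# comparison by t-test, and sign concordance with sequencing fold changes.

#' U6-normalized relative expression from cycle thresholds
#'
#' \code{2^-(ctTarget - ctReference)}: one cycle more than the reference
#' halves the relative expression. Adding a constant to both Ct values
#' leaves the result unchanged.
#'
#' @param ctTarget Target miRNA cycle threshold (vectorized).
#' @param ctReference Reference (U6 snRNA) cycle threshold.
#' @return Positive relative expression.
#' @examples
#' relativeExpression(25, 25)        # 1
#' relativeExpression(26, 25)        # 0.5
#' @export
relativeExpression <- function(ctTarget, ctReference) {
    if (any(!is.finite(ctTarget)) || any(!is.finite(ctReference)))
        stop("Ct values must be finite")
    2^(-(ctTarget - ctReference))
}

#' Read a qPCR measurement table
#'
#' Expects a TSV with columns \code{sample_id}, \code{group} (A =
#' treatment, B = control), \code{target}, \code{tech_rep},
#' \code{ct_target}, \code{ct_u6}.
#'
#' @param path Path to the TSV.
#' @return A \code{DataFrame} of measurements.
#' @export
readQpcrTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "target", "tech_rep", "ct_target",
              "ct_u6")
    if (!all(need %in% colnames(tab)))
        stop("qPCR table must have columns: ", paste(need, collapse = ", "))
    if (!all(tab$group %in% c("A", "B")))
        stop("group must be 'A' or 'B'")
    DataFrame(tab)
}

# per-sample relative expressions: technical replicates averaged on the
# Ct scale before exponentiation
.sampleRelExpr <- function(measurements) {
    key <- paste(measurements$group, measurements$sample_id, sep = "\r")
    ctT <- tapply(measurements$ct_target, key, mean)
    ctR <- tapply(measurements$ct_u6, key, mean)
    grp <- sub("\r.*", "", names(ctT))
    data.frame(group = grp,
               rel = relativeExpression(as.numeric(ctT), as.numeric(ctR)))
}

#' Compare qPCR expression between the two groups for one target
#'
#' Technical replicates are averaged on the Ct scale, each biological
#' sample contributes one \code{2^-dCt} value, and the groups are compared
#' with Welch's unequal-variance t-test. The log2 ratio is taken between
#' the group means of the relative expressions. When both groups are
#' identical constants the test is degenerate and p is reported as 1;
#' when both are constant but unequal, p is reported as the smallest
#' positive double.
#'
#' @param measurements A \code{DataFrame}/\code{data.frame} of
#'   measurements for one target (columns as in [readQpcrTable()]).
#' @return A list with \code{target}, \code{log2Ratio}, \code{pValue},
#'   \code{significant} (p < 0.05), \code{nA}, \code{nB}.
#' @export
compareQpcrGroups <- function(measurements) {
    target <- unique(measurements$target)
    if (length(target) != 1L)
        stop("measurements must cover exactly one target")
    rel <- .sampleRelExpr(measurements)
    a <- rel$rel[rel$group == "A"]
    b <- rel$rel[rel$group == "B"]
    if (length(a) < 2L || length(b) < 2L)
        stop("insufficient replicates: need >= 2 biological replicates ",
             "per group for target ", target)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
        p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1
             else .Machine$double.xmin
    } else {
        p <- t.test(a, b, var.equal = FALSE)$p.value
    }
    list(target = target,
         log2Ratio = log2(mean(a) / mean(b)),
         pValue = p,
         significant = p < 0.05,
         nA = length(a), nB = length(b))
}

#' qPCR results for every target in a measurement table
#'
#' @param measurements Full measurement table ([readQpcrTable()]).
#' @return A \code{DataFrame} with one row per target: \code{target},
#'   \code{log2Ratio}, \code{pValue}, \code{significant}, \code{nA},
#'   \code{nB}.
#' @export
qpcrResults <- function(measurements) {
    targets <- unique(measurements$target)
    rows <- lapply(targets, function(tg)
        compareQpcrGroups(measurements[measurements$target == tg, ,
                                       drop = FALSE]))
    DataFrame(target = vapply(rows, `[[`, "", "target"),
              log2Ratio = vapply(rows, `[[`, 1.0, "log2Ratio"),
              pValue = vapply(rows, `[[`, 1.0, "pValue"),
              significant = vapply(rows, `[[`, TRUE, "significant"),
              nA = vapply(rows, `[[`, 1L, "nA"),
              nB = vapply(rows, `[[`, 1L, "nB"))
}

#' Sign concordance between qPCR and sequencing fold changes
#'
#' @param qpcr A [qpcrResults()] table.
#' @param seqRes A [mirnaDiffExpr()] result (sequencing).
#' @return A \code{DataFrame} with per-target \code{qpcrLog2Ratio},
#'   \code{seqFoldChange}, \code{concordant} (NA when the target is
#'   missing from the sequencing table); \code{metadata()} holds the
#'   fraction concordant among matched targets.
#' @export
qpcrConcordance <- function(qpcr, seqRes) {
    m <- match(qpcr$target, seqRes$id)
    seqFc <- ifelse(is.na(m), NA_real_, seqRes$foldChange[m])
    conc <- ifelse(is.na(seqFc), NA,
                   sign(qpcr$log2Ratio) == sign(seqFc))
    out <- DataFrame(target = qpcr$target,
                     qpcrLog2Ratio = qpcr$log2Ratio,
                     seqFoldChange = seqFc,
                     concordant = conc)
    metadata(out) <- list(
        fractionConcordant = if (all(is.na(conc))) NA_real_
                             else mean(conc, na.rm = TRUE),
        nMissing = sum(is.na(conc)))
    out
}
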