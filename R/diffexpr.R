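# Normalization, fold change, exact-test p-values, significance labels,
# expression categories and reporting summaries.

#' Reads-per-million normalization
#'
#' \code{NE = count / totalClean * 1e6}. No zero substitution happens
#' here; see [applyZeroRule()].
#'
#' @param count Raw read count (vectorized).
#' @param totalClean Positive clean-read total of the library.
#' @return Normalized expression in reads per million.
#' @examples
#' normalizeRPM(1, 1e6)        # 1
#' normalizeRPM(138637, 9.23e6)
#' @export
normalizeRPM <- function(count, totalClean) {
    if (any(totalClean <= 0)) stop("totalClean must be positive")
    count / totalClean * 1e6
}

#' Zero substitution on the normalized-expression scale
#'
#' A normalized expression of exactly zero is revised to 0.01 RPM so that
#' fold changes stay finite for library-specific miRNAs; nonzero values
#' pass through unchanged.
#'
#' @param neA,neB Normalized expressions (vectorized).
#' @return A list with the revised \code{neA} and \code{neB}.
#' @examples
#' applyZeroRule(0, 12.5)      # 0.01, 12.5
#' @export
applyZeroRule <- function(neA, neB) {
    if (any(neA < 0) || any(neB < 0)) stop("normalized expression < 0")
    neA[neA == 0] <- 0.01
    neB[neB == 0] <- 0.01
    list(neA = neA, neB = neB)
}

#' Expression floor for differential-expression inclusion
#'
#' A miRNA enters differential-expression analysis only when its
#' normalized expression reaches \code{floor} in at least one library
#' (\code{max(neA, neB) >= floor}); requiring both would drop
#' library-specific miRNAs whose absent-library value is the 0.01
#' substitute.
#'
#' @param neA,neB Normalized expressions after [applyZeroRule()].
#' @param floor Inclusion floor in RPM.
#' @return Logical: included.
#' @examples
#' expressionFloor(0.01, 250)   # TRUE: library-specific stays testable
#' expressionFloor(0.4, 0.7)    # FALSE
#' @export
expressionFloor <- function(neA, neB, floor = 1) {
    pmax(neA, neB) >= floor
}

#' Log2 fold change between two normalized expressions
#'
#' \code{log2(neA / neB)} with A the treatment and B the control library.
#'
#' @param neA,neB Positive normalized expressions (after the zero rule).
#' @return Finite log2 ratio.
#' @examples
#' foldChange(10, 10)                                    # 0
#' foldChange(normalizeRPM(138637, 9.23e6),
#'            normalizeRPM(43703, 11.01e6))              # ~1.92
#' @export
foldChange <- function(neA, neB) {
    if (any(neA <= 0) || any(neB <= 0))
        stop("normalized expressions must be positive")
    log2(neA / neB)
}

#' Significance label from fold change and p-value
#'
#' \code{"**"} when \code{|fc| > 1} and \code{p < 0.01}; \code{"*"} when
#' \code{|fc| > 1} and \code{0.01 <= p < 0.05}; otherwise \code{"none"}.
#' A record is significantly differentially expressed iff its label is
#' not \code{"none"}.
#'
#' @param fc Log2 fold change (vectorized).
#' @param p P-value (vectorized).
#' @return Character vector of labels.
#' @examples
#' labelSignificance(1.92, 0.001)    # "**"
#' labelSignificance(0.5, 1e-9)      # "none"
#' @export
labelSignificance <- function(fc, p) {
    ifelse(abs(fc) > 1 & p < 0.01, "**",
    ifelse(abs(fc) > 1 & p < 0.05, "*", "none"))
}

#' Expression category from raw counts
#'
#' \code{A-specific} when the control count is zero and the treatment
#' count positive, \code{B-specific} for the converse, otherwise
#' \code{co-expressed}.
#'
#' @param countA,countB Raw counts (vectorized).
#' @return Character vector of categories.
#' @examples
#' categorize(10, 0)     # "A-specific"
#' @export
categorize <- function(countA, countB) {
    ifelse(countB == 0 & countA > 0, "A-specific",
    ifelse(countA == 0 & countB > 0, "B-specific", "co-expressed"))
}

#' Percentage rounded to two decimals, half up
#'
#' @param part,whole Non-negative counts with \code{part <= whole},
#'   \code{whole > 0}.
#' @return \code{100 * part / whole} rounded half-up to 2 decimals.
#' @examples
#' percentOf(471, 617)    # 76.34
#' percentOf(407, 617)    # 65.96
#' @export
percentOf <- function(part, whole) {
    if (any(whole <= 0)) stop("whole must be positive")
    if (any(part < 0) || any(part > whole))
        stop("part must lie in [0, whole]")
    floor(100 * part / whole * 100 + 0.5) / 100
}

#' Two-library differential expression of miRNAs
#'
#' Runs the full per-entity analysis on a [MirnaCountSet-class]: one
#' entity per detected mature arm (the hairpin id) and per detected star
#' arm (id suffixed \code{"*"}). For each entity the raw counts are
#' normalized to reads per million ([normalizeRPM()]), zeros substituted
#' ([applyZeroRule()]), the inclusion floor applied
#' ([expressionFloor()]), the fold change
#' \code{log2(treatment/control)} computed, and the exact conditional
#' test ([acPvalue()]) run on the raw counts with the library clean
#' totals. Significance labels follow [labelSignificance()]; categories
#' follow [categorize()] on raw counts. Records failing the floor keep
#' their computed statistics but are flagged \code{included = FALSE} and
#' are skipped by the significance tallies of [categorySummary()].
#'
#' @param x A [MirnaCountSet-class] with at least two libraries.
#' @param treatment,control Column names or indices of the treatment (A)
#'   and control (B) libraries.
#' @param floor Inclusion floor in RPM.
#' @param sided Tail convention of [acPvalue()].
#' @param includeStar Also test star-arm entities.
#' @param adjust \code{"none"} (default; the classical workflow applies no
#'   multiple-testing correction) or \code{"BH"} to add a
#'   Benjamini-Hochberg adjusted column \code{padj} (computed over
#'   included entities) without changing the labels.
#' @return A \code{DataFrame} with one row per entity: \code{id},
#'   \code{arm}, \code{countA}, \code{countB}, \code{neA}, \code{neB},
#'   \code{foldChange}, \code{pValue}, (\code{padj}), \code{sigLabel},
#'   \code{category}, \code{included}. \code{metadata()} records the
#'   treatment/control mapping and clean totals.
#' @export
mirnaDiffExpr <- function(x, treatment = 1L, control = 2L, floor = 1,
                          sided = "two_sided_min_doubled",
                          includeStar = TRUE,
                          adjust = c("none", "BH")) {
    stopifnot(is(x, "MirnaCountSet"), ncol(x) >= 2L)
    adjust <- match.arg(adjust)
    ti <- if (is.character(treatment)) match(treatment, colnames(x))
          else as.integer(treatment)
    ci <- if (is.character(control)) match(control, colnames(x))
          else as.integer(control)
    if (anyNA(c(ti, ci)) || ti == ci) stop("invalid library selection")
    tot <- colData(x)$cleanTotal

    m <- matureCounts(x); s <- starCounts(x)
    selM <- m[, ti] > 0 | m[, ci] > 0
    selS <- includeStar & (s[, ti] > 0 | s[, ci] > 0)
    starIds <- if (any(selS)) paste0(rownames(x)[selS], "*")
               else character(0)
    ids <- c(rownames(x)[selM], starIds)
    arm <- c(rep("mature", sum(selM)), rep("star", sum(selS)))
    cA <- unname(c(m[selM, ti], s[selS, ti]))
    cB <- unname(c(m[selM, ci], s[selS, ci]))

    neA <- normalizeRPM(cA, tot[ti])
    neB <- normalizeRPM(cB, tot[ci])
    ne <- applyZeroRule(neA, neB)
    included <- expressionFloor(ne$neA, ne$neB, floor)
    fc <- if (length(cA)) foldChange(ne$neA, ne$neB) else numeric(0)
    p <- if (length(cA)) acPvalue(cA, cB, tot[ti], tot[ci], sided = sided)
         else numeric(0)

    res <- DataFrame(id = ids, arm = arm,
                     countA = cA, countB = cB,
                     neA = ne$neA, neB = ne$neB,
                     foldChange = fc, pValue = p)
    if (adjust == "BH") {
        res$padj <- NA_real_
        res$padj[included] <- p.adjust(p[included], method = "BH")
    }
    res$sigLabel <- labelSignificance(fc, p)
    res$category <- categorize(cA, cB)
    res$included <- included
    o <- order(res$arm, res$id)
    res <- res[o, ]
    metadata(res) <- list(treatment = colnames(x)[ti],
                          control = colnames(x)[ci],
                          cleanTotals = setNames(tot[c(ti, ci)],
                                                 colnames(x)[c(ti, ci)]),
                          floor = floor, sided = sided)
    res
}

#' Category and significance summary of a differential-expression table
#'
#' Reports the unique-entity total, the expression-category breakdown
#' (co-expressed / A-specific / B-specific) with percentages
#' ([percentOf()]), the number of significantly differentially expressed
#' entities (label not \code{"none"} among included records), and the
#' up/down split with its category sub-breakdown.
#'
#' @param res A [mirnaDiffExpr()] result.
#' @return A named list of counts and percentages.
#' @export
categorySummary <- function(res) {
    n <- nrow(res)
    if (n == 0L)
        return(list(nTotal = 0L, nCoexpressed = 0L, nASpecific = 0L,
                    nBSpecific = 0L, pctCoexpressed = NA_real_,
                    pctASpecific = NA_real_, pctBSpecific = NA_real_,
                    nSignificant = 0L, pctSignificant = NA_real_,
                    nUp = 0L, nDown = 0L,
                    nUpASpecific = 0L, nUpCoexpressed = 0L,
                    nDownBSpecific = 0L, nDownCoexpressed = 0L))
    sig <- res$included & res$sigLabel != "none"
    up <- sig & res$foldChange > 0
    down <- sig & res$foldChange < 0
    list(
        nTotal = n,
        nCoexpressed = sum(res$category == "co-expressed"),
        nASpecific = sum(res$category == "A-specific"),
        nBSpecific = sum(res$category == "B-specific"),
        pctCoexpressed = percentOf(sum(res$category == "co-expressed"), n),
        pctASpecific = percentOf(sum(res$category == "A-specific"), n),
        pctBSpecific = percentOf(sum(res$category == "B-specific"), n),
        nSignificant = sum(sig),
        pctSignificant = percentOf(sum(sig), n),
        nUp = sum(up),
        nDown = sum(down),
        nUpASpecific = sum(up & res$category == "A-specific"),
        nUpCoexpressed = sum(up & res$category == "co-expressed"),
        nDownBSpecific = sum(down & res$category == "B-specific"),
        nDownCoexpressed = sum(down & res$category == "co-expressed"))
}

#' Most highly expressed entities in one library
#'
#' @param res A [mirnaDiffExpr()] result.
#' @param library \code{"A"} (treatment) or \code{"B"} (control).
#' @param n Number of entities to return.
#' @return The top rows of \code{res} ordered by descending normalized
#'   expression in the chosen library, ties broken by id.
#' @export
topExpressed <- function(res, library = c("A", "B"), n = 10L) {
    library <- match.arg(library)
    if (n < 1L) stop("n must be >= 1")
    ne <- if (library == "A") res$neA else res$neB
    o <- order(-ne, res$id)
    res[head(o, n), ]
}
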