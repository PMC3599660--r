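# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately re-derive results by enumeration or
# closed form and never call the implementation paths they check.

rcDNA <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                                  collapse = ""))

# enumerate every adapter start; pick max overlap, then min mismatches,
# then leftmost
bruteTrim <- function(read, adapter, minOverlap = 6L, rate = 0.1) {
    L <- nchar(read); la <- nchar(adapter)
    r <- strsplit(read, "")[[1]]; a <- strsplit(adapter, "")[[1]]
    best <- NULL
    for (p in 0:(L - minOverlap)) {
        if (p < 0) next
        o <- min(la, L - p)
        m <- sum(r[p + seq_len(o)] != a[seq_len(o)])
        if (m > floor(rate * o + 1e-9)) next
        cand <- c(o = o, m = m, p = p)
        if (is.null(best) || cand["o"] > best["o"] ||
            (cand["o"] == best["o"] && cand["m"] < best["m"]))
            best <- cand
    }
    if (is.null(best)) NA_character_ else substr(read, 1, best[["p"]])
}

# enumerate all (ref, shift) alignments; replicate the tie-break order
# fewest mismatches > smallest |offset| > negative offset > earlier ref
bruteMatch <- function(tag, refs, maxSub = 2L, maxShift = 2L) {
    t <- strsplit(tag, "")[[1]]; lt <- length(t)
    best <- NULL
    for (k in seq_along(refs)) {
        r <- strsplit(refs[k], "")[[1]]; lr <- length(r)
        need <- min(lt, lr) - maxShift
        for (s in -maxShift:maxShift) {
            i0 <- max(1L, 1L - s); i1 <- min(lt, lr - s)
            ov <- i1 - i0 + 1L
            if (ov < need || ov <= 0L) next
            m <- sum(t[i0:i1] != r[(i0:i1) + s])
            if (m > maxSub) next
            better <- is.null(best) || m < best$m ||
                (m == best$m && (abs(s) < abs(best$s) ||
                                 (abs(s) == abs(best$s) && s < best$s)))
            if (better) best <- list(ref = k, m = m, s = s)
        }
    }
    best
}

# minimal mismatch count of star against revcomp(mature) over small shifts
duplexMismatches <- function(mature, star, maxShift = 4L) {
    rc <- rcDNA(mature)
    r <- strsplit(rc, "")[[1]]; s <- strsplit(star, "")[[1]]
    lr <- length(r); ls <- length(s)
    best <- Inf
    for (sh in -maxShift:maxShift) {
        i0 <- max(1L, 1L - sh); i1 <- min(ls, lr - sh)
        if (i1 - i0 + 1L < min(lr, ls) - maxShift) next
        best <- min(best, sum(s[i0:i1] != r[(i0:i1) + sh]))
    }
    best
}

# negative-binomial closed form of the conditional count distribution
oracleProb <- function(y, x, n1, n2) dnbinom(y, size = x + 1,
                                             prob = n1 / (n1 + n2))
oracleLower <- function(y, x, n1, n2) pnbinom(y, size = x + 1,
                                              prob = n1 / (n1 + n2))
oracleUpper <- function(y, x, n1, n2) {
    if (y == 0) 1
    else pnbinom(y - 1, size = x + 1, prob = n1 / (n1 + n2),
                 lower.tail = FALSE)
}

# textbook Welch two-sample t-test
welchOracle <- function(a, b) {
    v1 <- var(a) / length(a); v2 <- var(b) / length(b)
    tt <- (mean(a) - mean(b)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
    2 * pt(-abs(tt), df)
}

# small shared fixture: catalog + paired zero-noise / noisy libraries
smallExperiment <- function(seed = 5L, zeroNoise = TRUE, nReads = 5000L) {
    simulateExperiment(nMirnas = 30, nReads = nReads, nDE = 4,
                       nSpecificA = 2, nSpecificB = 2,
                       minExpectedCount = 30, seed = seed,
                       zeroNoise = zeroNoise)
}

# run one simulated library through cleaning + annotation
annotateLib <- function(lib, spec, sim) {
    cl <- cleanReads(list(sequences = lib$sequences,
                          qualities = lib$qualities),
                     adapter = spec@adapter, adapter5 = spec@adapter5)
    an <- classifyTags(collapseReads(cl$reads), sim$catalog,
                       sim$contaminants)
    list(clean = cl, annot = an)
}
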