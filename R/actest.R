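#' Exact conditional count test for two sequencing libraries
#'
#' For a transcript observed \code{x} times among \code{N1} clean reads in
#' library 1, the probability of observing \code{y} occurrences among
#' \code{N2} clean reads in library 2, conditional on \code{x}, is
#' \deqn{p(y|x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!}
#'   \left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)}}{
#'   p(y|x) = (N2/N1)^y (x+y)!/(x! y!) (1+N2/N1)^-(x+y+1)}
#' This is the classical exact test for pairwise library comparisons of
#' counts; as a function of \code{y} it is a negative-binomial distribution
#' with size \code{x+1} and success probability \code{N1/(N1+N2)}.
#' \code{acProbability} evaluates the probability mass in log space (safe
#' for counts up to at least 1e7); \code{acPvalue} forms tail sums: the
#' lower tail \code{C = sum(p(k|x), k <= y)}, the upper tail
#' \code{D = sum(p(k|x), k >= y)}, or the doubled minimal tail
#' \code{min(1, 2 min(C, D))} (the default two-sided p-value).
#'
#' Tails are accumulated stably: the smaller tail is summed directly (the
#' lower tail through a log-sum-exp over \code{k = 0..y}; the upper tail
#' through the term recurrence
#' \code{p(k+1|x)/p(k|x) = ((x+k+1)/(k+1)) (N2/N1)/(1+N2/N1)} until terms
#' fall below 1e-17 of the accumulated sum) and the other tail is obtained
#' from the complement \code{C + D = 1 + p(y|x)}.
#'
#' @param y Count in library 2 (non-negative integer; vectorized).
#' @param x Count in library 1 (non-negative integer; vectorized).
#' @param n1,n2 Total clean reads of libraries 1 and 2 (positive).
#' @param sided One of \code{"two_sided_min_doubled"} (default),
#'   \code{"lower"}, \code{"upper"}.
#' @return \code{acProbability}: probability mass p(y|x) in (0, 1).
#'   \code{acPvalue}: p-value in (0, 1].
#' @examples
#' acProbability(0, 0, 1e6, 1e6)            # 0.5
#' acPvalue(5, 5, 1e6, 1e6)                 # ~1: no evidence of change
#' acPvalue(100, 200, 1e6, 1e6)             # strong change
#' @export
acProbability <- function(y, x, n1, n2) {
    .acCheck(x, y, n1, n2)
    exp(.acLogProb(y, x, n2 / n1))
}

.acCheck <- function(x, y, n1, n2) {
    if (length(x) == 0L || length(y) == 0L)
        stop("empty input")
    if (any(n1 <= 0) || any(n2 <= 0))
        stop("library totals must be positive")
    if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y)))
        stop("counts must be non-negative integers")
    invisible(TRUE)
}

.acLogProb <- function(k, x, q) {
    k * log(q) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
        (x + k + 1) * log1p(q)
}

# both tails (lower C, upper D) for scalar x, y
.acTails <- function(x, y, n1, n2) {
    q <- n2 / n1
    tfrac <- q / (1 + q)
    lpy <- .acLogProb(y, x, q)
    py <- exp(lpy)
    mu <- (x + 1) * q              # mean of p(.|x)
    if (y <= mu) {
        lp <- .acLogProb(seq.int(0L, y), x, q)
        m <- max(lp)
        C <- exp(m) * sum(exp(lp - m))
        C <- min(C, 1)
        D <- min(1, max(1 - C + py, py))
    } else {
        term <- 1; S <- 1; k <- y
        repeat {
            r <- ((x + k + 1) / (k + 1)) * tfrac
            term <- term * r
            S <- S + term
            k <- k + 1
            if (r < 1 && term < 1e-17 * S) break
        }
        D <- min(1, py * S)
        C <- min(1, max(1 - D + py, py))
    }
    c(lower = C, upper = D)
}

#' @rdname acProbability
#' @export
acPvalue <- function(x, y, n1, n2,
                     sided = c("two_sided_min_doubled", "lower", "upper")) {
    sided <- match.arg(sided)
    .acCheck(x, y, n1, n2)
    n <- max(length(x), length(y), length(n1), length(n2))
    x <- rep_len(x, n); y <- rep_len(y, n)
    n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
    vapply(seq_len(n), function(i) {
        tails <- .acTails(x[i], y[i], n1[i], n2[i])
        p <- switch(sided,
            lower = tails[["lower"]],
            upper = tails[["upper"]],
            two_sided_min_doubled = min(1, 2 * min(tails)))
        min(max(p, .Machine$double.xmin), 1)
    }, numeric(1))
}
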