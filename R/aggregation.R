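## Aggregating statistics: combine m per-subset results into one
## pathway-level result.

#' Fisher's method for combining p-values
#'
#' Combines `m` per-subset p-values into \eqn{T = -2 \sum_i \ln p_i}, with a
#' secondary reference p-value from the upper tail of a chi-square
#' distribution with `2m` degrees of freedom (exact for independent uniform
#' p-values). Within the permutation engine, `T` is instead compared to its
#' own permutation distribution; the chi-square value is reported alongside.
#'
#' @param p numeric vector of p-values, each in `(0, 1]`.
#' @return list with elements `T` (the combined statistic) and
#'   `p.chisq` (upper-tail chi-square probability on `2 * length(p)` df).
#' @examples
#' fisherCombine(c(0.1, 0.2))  # T ~ 7.824, p.chisq ~ 0.0982
#' @export
fisherCombine <- function(p) {
    checkPValues(p)
    T <- -2 * sum(log(p))
    list(T = T, p.chisq = stats::pchisq(T, df = 2 * length(p),
                                        lower.tail = FALSE))
}

#' SUMSTAT aggregation
#'
#' Sums the per-subset single-set statistics: \eqn{T = \sum_j t_j}. With the
#' squared variance-component statistic this sum is invariant to the choice
#' of partition and equals the single-set statistic.
#'
#' @param t numeric vector of non-negative, finite per-subset statistics.
#' @return scalar sum.
#' @export
sumstatCombine <- function(t) {
    if (length(t) == 0L)
        stop("need at least one subset statistic")
    if (!all(is.finite(t)))
        stop("subset statistics must be finite")
    sum(t)
}

#' Bonferroni (min-p) decision rule
#'
#' Declares a set of `m` subset tests significant when the smallest
#' per-subset p-value falls strictly below `alpha / m`. Reports the minimum
#' p-value and the cutoff rather than an adjusted p-value.
#'
#' @param p numeric vector of per-subset p-values in `(0, 1]`.
#' @param alpha family-wise significance level in `(0, 1)`; default 0.05.
#' @return list with `min.p`, `threshold` (`alpha/m`) and `significant`.
#' @examples
#' bonferroniDecision(c(0.019, 0.3, 0.5, 0.8))  # threshold 0.0125, not significant
#' @export
bonferroniDecision <- function(p, alpha = 0.05) {
    checkPValues(p)
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
        stop("'alpha' must be a single value in (0, 1)")
    m <- length(p)
    minP <- min(p)
    threshold <- alpha / m
    list(min.p = minP, threshold = threshold,
         significant = minP < threshold)
}

checkPValues <- function(p) {
    if (length(p) == 0L)
        stop("need at least one p-value")
    if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    invisible(p)
}
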