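## Single-set test statistics.
##
## The variance-component statistic is VC = ||F+ - F-||, the Euclidean
## distance between the case and control allele-frequency vectors: for
## variant h, an element of F+ is the count of minor alleles among the cases
## divided by the number of case chromosomes (2 x number of cases with a
## non-missing genotype at h). This is a simplified, mathematically
## equivalent form of the SKAT variance-component statistic for the
## unweighted linear kernel, up to a monotone transform, which leaves
## permutation p-values unchanged.

## Per-variant allele frequency in one group, complete-case denominators.
## counts: l x N; members: logical/index over samples.
.groupFreq <- function(counts, members) {
    sub <- counts[, members, drop = FALSE]
    nonmiss <- rowSums(!is.na(sub))
    if (any(nonmiss == 0L))
        stop("variant(s) entirely missing within the group: ",
             paste(rownames(counts)[nonmiss == 0L], collapse = ", "))
    rowSums(sub, na.rm = TRUE) / (2 * nonmiss)
}

#' Allele-frequency vector for cases or controls
#'
#' For each variant, the count of minor alleles in the group divided by the
#' number of chromosomes carried by group members with a non-missing
#' genotype at that variant (complete-case denominator, `2 * n_nonmissing`).
#'
#' @param x a [GenotypeExperiment-class].
#' @param group `"case"` or `"control"`.
#' @return named numeric vector of length `nrow(x)`, values in `[0, 1]`.
#' @examples
#' cnt <- matrix(c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L), nrow = 2,
#'               dimnames = list(c("v1", "v2"), paste0("s", 1:4)))
#' ge <- GenotypeExperiment(cnt, status = c(1, 1, 0, 0))
#' alleleFreq(ge, "case")    # v1: 1/4, v2: 2/4
#' alleleFreq(ge, "control") # v1: 0,   v2: 1/4
#' @export
#' @name alleleFreq
setMethod("alleleFreq", "GenotypeExperiment", function(x, group = c("case", "control")) {
    group <- match.arg(group)
    members <- caseControl(x) == group
    if (!any(members))
        stop("group '", group, "' is empty")
    .groupFreq(genotypeCounts(x), members)
})

#' Variance-component statistic VC = ||F+ - F-||
#'
#' The Euclidean norm of the difference between the case and control
#' allele-frequency vectors over all variants in `x`. Zero exactly when the
#' two frequency vectors coincide; sensitive to frequency differences in
#' either direction, unlike a burden statistic.
#'
#' @param x a [GenotypeExperiment-class].
#' @param squared if `TRUE` return the squared norm
#'   \eqn{\sum_h (F^+_h - F^-_h)^2}. The squared form is additive over any
#'   variant partition, which makes SUMSTAT aggregation of it identical to
#'   the single-set test; the unsquared norm is the default reported form.
#' @return non-negative scalar.
#' @export
#' @name vcStat
setMethod("vcStat", "GenotypeExperiment", function(x, squared = FALSE) {
    d <- alleleFreq(x, "case") - alleleFreq(x, "control")
    ss <- sum(d^2)
    if (squared) ss else sqrt(ss)
})

#' Generic burden statistic
#'
#' The absolute value of the signed sum of per-variant allele-frequency
#' differences, \eqn{|\sum_h (F^+_h - F^-_h)|}. Effects of opposite sign
#' cancel, the defining contrast with the variance-component statistic.
#' Provided for comparison only; the multi-set engine treats it as just
#' another single-set statistic.
#'
#' @param x a [GenotypeExperiment-class].
#' @return non-negative scalar.
#' @export
#' @name burdenStat
setMethod("burdenStat", "GenotypeExperiment", function(x) {
    d <- alleleFreq(x, "case") - alleleFreq(x, "control")
    abs(sum(d))
})
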