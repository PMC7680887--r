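## Multi-set testing engine.
##
## Strategy: (1) split the l variants into m mutually exclusive, exhaustive
## subsets; (2) compute the single-set statistic t_i on each subset;
## (3) permute case/control status P times and recompute, giving s_ki;
## (4) aggregate the subset evidence (Fisher's, SUMSTAT or a Bonferroni
## min-p rule) and compare the observed aggregate T to its permutation
## distribution T_1..T_P.
##
## All subsets share the SAME P permutations, preserving the dependence
## between subsets under the null, and everything is derived from one
## l x (P+1) matrix of per-variant case/control frequency differences, so
## the per-permutation cost is a pair of matrix products.

## Permutation indices: N x P matrix, column k a uniform shuffle of 1..N.
.permIndices <- function(N, P, seed) {
    set.seed(seed)
    vapply(seq_len(P), function(k) sample.int(N), integer(N))
}

## Case-indicator matrix: column 1 observed labels, then P permutations.
.indicatorMatrix <- function(status, perms) {
    z <- as.numeric(status == "case")
    cbind(z, matrix(z[perms], nrow = length(z)), deparse.level = 0)
}

## Per-variant frequency differences F+ - F- under each relabelling.
## counts: l x N with NA allowed; Z: N x K case indicators.
## Complete-case denominators per variant per relabelling.
.freqDeltaPool <- function(counts, Z) {
    C0 <- counts
    C0[is.na(C0)] <- 0L
    storage.mode(C0) <- "double"
    nm <- matrix(as.numeric(!is.na(counts)), nrow = nrow(counts))
    caseCnt <- C0 %*% Z
    caseN <- nm %*% Z
    ctrlCnt <- rowSums(C0) - caseCnt
    ctrlN <- rowSums(nm) - caseN
    if (any(caseN == 0) || any(ctrlN == 0))
        stop("a variant has no non-missing genotype in one group under ",
             "some relabelling; remove variants with extreme missingness")
    caseCnt / (2 * caseN) - ctrlCnt / (2 * ctrlN)
}

## Per-subset statistics from the frequency-difference pool.
## delta: l x K; part: factor length l. Returns m x K (rows in level order).
.subsetStatPool <- function(delta, part, stat) {
    part <- factor(part)
    S <- switch(stat,
        vc     = sqrt(rowsum(delta^2, part, reorder = FALSE)),
        vc2    = rowsum(delta^2, part, reorder = FALSE),
        burden = abs(rowsum(delta, part, reorder = FALSE)),
        stop("unknown statistic '", stat, "'"))
    S[levels(part), , drop = FALSE]
}

## Rank-based p-values within each pool column {t_i} U {s_1i..s_Pi}:
## p = #{x in pool >= value} / (P + 1). For the observed value this equals
## the add-one estimator (1 + #{s_ki >= t_i}) / (P + 1).
## Statistics are rounded to 12 significant digits first so that
## mathematically tied relabellings (e.g. case/control complements) rank as
## ties regardless of floating-point summation order; genuine differences
## between count-based statistics are many orders of magnitude larger.
## S: m x (P+1), column 1 observed. Returns matrix of the same shape.
.poolRankP <- function(S) {
    K <- ncol(S)
    S <- signif(S, 12)
    t(apply(S, 1L, function(v) (K + 1 - rank(v, ties.method = "min")) / K))
}

.resolvePartition <- function(x, subsets) {
    if (is.null(subsets)) {
        part <- variantSubsets(x)
        if (is.null(part))
            part <- factor(rep("set1", nrow(x)))
        return(part)
    }
    if (!is.null(names(subsets))) {
        unknown <- setdiff(names(subsets), rownames(x))
        if (length(unknown))
            stop("partition references unknown variant(s): ",
                 paste(unknown, collapse = ", "))
        miss <- setdiff(rownames(x), names(subsets))
        if (length(miss))
            stop("partition is not exhaustive; unassigned variant(s): ",
                 paste(miss, collapse = ", "))
        subsets <- subsets[rownames(x)]
    }
    if (length(subsets) != nrow(x))
        stop("'subsets' must assign every variant exactly once")
    if (!is.factor(subsets))
        subsets <- factor(subsets, levels = unique(as.character(subsets)))
    droplevels(subsets)
}

#' Permute case/control labels
#'
#' Generates `P` uniform random shuffles of a label vector, reproducibly
#' from a seed. Case and control totals are conserved by construction.
#'
#' @param y label vector (factor or character).
#' @param P number of permutations, `>= 1`.
#' @param seed integer RNG seed.
#' @return list of `P` permuted copies of `y`.
#' @export
permuteLabels <- function(y, P, seed = 1L) {
    stopifnot(P >= 1)
    perms <- .permIndices(length(y), P, seed)
    lapply(seq_len(P), function(k) y[perms[, k]])
}

#' Build the permutation pool of per-subset statistics
#'
#' Computes the observed statistics \eqn{t_1..t_m} on each subset of the
#' partition and the statistics \eqn{s_{k1}..s_{km}} under `P` random
#' permutations of case/control status, with the same permutations applied
#' to every subset.
#'
#' @param x a [GenotypeExperiment-class].
#' @param stat single-set statistic: `"vc"` (Euclidean norm of the
#'   case-control frequency difference, the default), `"vc2"` (its square)
#'   or `"burden"` (absolute signed frequency-difference sum).
#' @param P number of permutations.
#' @param seed integer RNG seed governing the permutations.
#' @param subsets optional partition overriding `variantSubsets(x)`; with
#'   neither set, all variants form one subset.
#' @return a [PermutationPool-class].
#' @export
buildPermutationPool <- function(x, stat = c("vc", "vc2", "burden"),
                                 P = 999L, seed = 1L, subsets = NULL) {
    stat <- match.arg(stat)
    stopifnot(P >= 1)
    part <- .resolvePartition(x, subsets)
    S <- .statPoolMatrix(x, part, stat, P, seed)
    new("PermutationPool",
        observed = stats::setNames(S[, 1L], rownames(S)),
        permuted = t(S[, -1L, drop = FALSE]),
        P = as.integer(P), statistic = stat, seed = as.integer(seed))
}

## Shared workhorse: m x (P+1) statistic matrix, column 1 observed.
.statPoolMatrix <- function(x, part, stat, P, seed) {
    perms <- .permIndices(ncol(x), P, seed)
    Z <- .indicatorMatrix(caseControl(x), perms)
    delta <- .freqDeltaPool(genotypeCounts(x), Z)
    .subsetStatPool(delta, part, stat)
}

#' Per-subset permutation p-values from a pool
#'
#' For subset `i`, the observed p-value is
#' \eqn{p_i = (1 + \#\{k : s_{ki} \ge t_i\}) / (P + 1)}, and each permuted
#' replicate receives the rank-based p-value of `s_ki` within the pooled
#' column \eqn{\{t_i, s_{1i}, \ldots, s_{Pi}\}} (ties counted as "at least
#' as extreme"). All values lie on the grid `1/(P+1), ..., 1`, so they are
#' strictly positive and safe to log.
#'
#' @param pool a [PermutationPool-class].
#' @return list with `observed` (length `m`) and `permuted` (`P x m` matrix).
#' @export
poolPValues <- function(pool) {
    S <- cbind(pool@observed, t(pool@permuted), deparse.level = 0)
    Pm <- .poolRankP(S)
    list(observed = stats::setNames(Pm[, 1L], names(pool@observed)),
         permuted = t(Pm[, -1L, drop = FALSE]))
}

## Aggregate an m x (P+1) statistic matrix into a test outcome.
.aggregateS <- function(S, aggregator, alpha, P) {
    m <- nrow(S)
    Pm <- .poolRankP(S)
    obs.p <- stats::setNames(Pm[, 1L], rownames(S))
    obs.t <- stats::setNames(S[, 1L], rownames(S))
    chisq.p <- NA_real_
    threshold <- NA_real_
    if (aggregator == "bonferroni") {
        dec <- bonferroniDecision(obs.p, alpha)
        return(list(statistic = dec$min.p, p.value = NA_real_,
                    chisq.p = NA_real_, subset.p = obs.p, subset.stat = obs.t,
                    threshold = dec$threshold, significant = dec$significant))
    }
    Tall <- switch(aggregator,
        fisher = -2 * colSums(log(Pm)),
        sumstat = ,
        `single-set` = colSums(S),
        stop("unknown aggregator '", aggregator, "'"))
    Tall <- signif(Tall, 12)  # same tie rationale as .poolRankP
    Tobs <- Tall[1L]
    pval <- (1 + sum(Tall[-1L] >= Tobs)) / (P + 1)
    if (aggregator == "fisher")
        chisq.p <- stats::pchisq(Tobs, df = 2 * m, lower.tail = FALSE)
    list(statistic = unname(Tobs), p.value = pval, chisq.p = chisq.p,
         subset.p = obs.p, subset.stat = obs.t, threshold = threshold,
         significant = pval <= alpha)
}

#' Multi-set association test
#'
#' Runs the full multi-set strategy on a partitioned genotype matrix:
#' per-subset variance-component (or burden) statistics, a shared
#' permutation pool, per-subset permutation p-values, and one of three
#' aggregators. `"fisher"` combines the per-subset p-values with
#' \eqn{T = -2\sum \ln p_i} and compares `T` to its permutation
#' distribution (the chi-square reference on `2m` df is reported as a
#' secondary value); `"sumstat"` sums the subset statistics and compares the
#' sum to its permutation distribution; `"bonferroni"` reports the minimum
#' per-subset p-value and declares significance when it falls strictly
#' below `alpha/m` (a decision rule, not a permutation p-value).
#'
#' @inheritParams buildPermutationPool
#' @param aggregator `"fisher"`, `"sumstat"` or `"bonferroni"`.
#' @param alpha significance level used for the reported decision (and the
#'   Bonferroni cutoff `alpha/m`).
#' @return a [MultisetResult-class].
#' @examples
#' cfg <- makeScenario(1, m = 4, l = 64, nCausal = 8, nCases = 50,
#'                     nControls = 50, rr = 2)
#' ge <- simulateDataset(cfg, seed = 7)
#' multisetTest(ge, "fisher", P = 99, seed = 7)
#' @export
multisetTest <- function(x, aggregator = c("fisher", "sumstat", "bonferroni"),
                         stat = c("vc", "vc2", "burden"), P = 999L,
                         seed = 1L, alpha = 0.05, subsets = NULL) {
    aggregator <- match.arg(aggregator)
    stat <- match.arg(stat)
    stopifnot(P >= 1)
    part <- .resolvePartition(x, subsets)
    S <- .statPoolMatrix(x, part, stat, P, seed)
    res <- .aggregateS(S, aggregator, alpha, P)
    .newResult(res, aggregator, stat, nlevels(part), P, seed, alpha)
}

#' Single-set association test
#'
#' The m = 1 special case of the multi-set strategy: one statistic on all
#' variants, compared to its permutation distribution. Identical to
#' [multisetTest()] with a one-subset partition under either the Fisher or
#' SUMSTAT aggregator.
#'
#' @inheritParams buildPermutationPool
#' @param alpha significance level for the reported decision.
#' @return a [MultisetResult-class] with `aggregator = "single-set"`.
#' @export
singleSetTest <- function(x, stat = c("vc", "vc2", "burden"), P = 999L,
                          seed = 1L, alpha = 0.05) {
    stat <- match.arg(stat)
    stopifnot(P >= 1)
    part <- factor(rep("all", nrow(x)))
    S <- .statPoolMatrix(x, part, stat, P, seed)
    res <- .aggregateS(S, "single-set", alpha, P)
    .newResult(res, "single-set", stat, 1L, P, seed, alpha)
}

.newResult <- function(res, aggregator, stat, m, P, seed, alpha) {
    new("MultisetResult", aggregator = aggregator,
        statistic = res$statistic, p.value = res$p.value,
        chisq.p = res$chisq.p, subset.p = res$subset.p,
        subset.stat = res$subset.stat, threshold = res$threshold,
        significant = res$significant, statisticName = stat,
        m = as.integer(m), P = as.integer(P), seed = as.integer(seed),
        alpha = alpha)
}

#' @describeIn multisetTest display method for test results.
#' @param object a `MultisetResult`.
#' @export
setMethod("show", "MultisetResult", function(object) {
    cat(sprintf("MultisetResult: %s aggregation of %d subset(s), statistic '%s'\n",
                object@aggregator, object@m, object@statisticName))
    if (object@aggregator == "bonferroni") {
        cat(sprintf("  min p = %.4g, cutoff alpha/m = %.4g -> %ssignificant\n",
                    object@statistic, object@threshold,
                    if (object@significant) "" else "NOT "))
    } else {
        cat(sprintf("  T = %.4g, permutation p = %.4g (P = %d)%s\n",
                    object@statistic, object@p.value, object@P,
                    if (!is.na(object@chisq.p))
                        sprintf(", chi-square p = %.4g", object@chisq.p)
                    else ""))
    }
    if (object@m > 1L) {
        cat("  per-subset p-values:\n")
        print(signif(object@subset.p, 4))
    }
    invisible(object)
})

#' @describeIn multisetTest one-row-per-subset data.frame plus an aggregate
#'   row (`set = "_aggregate_"`), the layout written by [writeResults()].
#' @param x a `MultisetResult`.
#' @param row.names,optional,... ignored; present for S3/S4 compatibility.
#' @export
setMethod("as.data.frame", "MultisetResult",
    function(x, row.names = NULL, optional = FALSE, ...) {
    sets <- data.frame(
        set = names(x@subset.p), aggregator = x@aggregator,
        statistic = unname(x@subset.stat), p_value = unname(x@subset.p),
        stringsAsFactors = FALSE)
    agg <- data.frame(
        set = "_aggregate_", aggregator = x@aggregator,
        statistic = x@statistic, p_value = x@p.value,
        stringsAsFactors = FALSE)
    out <- rbind(agg, sets)
    out$m <- x@m
    out$P <- x@P
    out$seed <- x@seed
    out$alpha <- x@alpha
    out$stat <- x@statisticName
    out
})

#' @describeIn buildPermutationPool display method.
#' @param object a `PermutationPool`.
#' @export
setMethod("show", "PermutationPool", function(object) {
    cat(sprintf("PermutationPool: %d subset(s), P = %d, statistic '%s', seed %d\n",
                length(object@observed), object@P, object@statistic,
                object@seed))
    cat("  observed: ", paste(signif(object@observed, 4), collapse = ", "),
        "\n", sep = "")
    invisible(object)
})
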