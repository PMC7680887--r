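#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GenotypeExperiment: minor-allele counts with a case/control phenotype
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a single
#' `"counts"` assay of minor-allele counts (rows are variants, columns are
#' samples; each entry 0, 1, 2 or `NA`), a binary `status` column in
#' `colData` (levels `"control"` and `"case"`), and an optional `subset`
#' column in `rowData` assigning each variant to one of `m` mutually
#' exclusive, exhaustive subsets.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [GenotypeExperiment()] for construction,
#'   [genotypeCounts()], [caseControl()], [variantSubsets()] for access.
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        ok <- is.na(cnt) | cnt == 0L | cnt == 1L | cnt == 2L
        if (!all(ok))
            msg <- c(msg, "genotype counts must be 0, 1, 2 or NA")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"status" %in% colnames(cd))
        msg <- c(msg, "colData column 'status' is required")
    else {
        st <- cd$status
        if (!is.factor(st) || !identical(levels(st), c("control", "case")))
            msg <- c(msg, "'status' must be a factor with levels control, case")
        else if (sum(st == "case") < 1L || sum(st == "control") < 1L)
            msg <- c(msg, "at least one case and one control are required")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "variant ids (rownames) must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be unique")
    rd <- SummarizedExperiment::rowData(object)
    if ("subset" %in% colnames(rd)) {
        part <- rd$subset
        if (anyNA(part))
            msg <- c(msg, "variant subsets must be exhaustive (no NA labels)")
        else if (is.factor(part) && !all(levels(part) %in% as.character(part)))
            msg <- c(msg, "every subset must contain at least one variant")
    }
    if (is.null(msg)) TRUE else msg
})

#' PermutationPool: observed and permuted per-subset statistics
#'
#' Holds the observed single-set statistics \eqn{t_1 \ldots t_m} for the `m`
#' subsets of a variant partition and the corresponding statistics
#' \eqn{s_{k1} \ldots s_{km}} recomputed under `P` random permutations of
#' case/control status. The same `P` permutations are shared by all subsets,
#' preserving cross-subset dependence under the null.
#'
#' @slot observed numeric vector of length `m`: statistics on true labels.
#' @slot permuted numeric `P x m` matrix: statistics under permuted labels.
#' @slot P integer, number of permutations.
#' @slot statistic character, one of `"vc"`, `"vc2"`, `"burden"`.
#' @slot seed integer seed the permutations were generated from.
#' @export
setClass("PermutationPool",
    representation(observed = "numeric", permuted = "matrix",
                   P = "integer", statistic = "character", seed = "integer"))

setValidity("PermutationPool", function(object) {
    msg <- NULL
    m <- length(object@observed)
    if (!identical(dim(object@permuted), c(object@P, m)))
        msg <- c(msg, "permuted must be a P x m matrix")
    if (!all(is.finite(object@permuted)) || !all(is.finite(object@observed)))
        msg <- c(msg, "all statistics must be finite")
    if (any(object@permuted < 0) || any(object@observed < 0))
        msg <- c(msg, "all statistics must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' MultisetResult: outcome of a single- or multi-set association test
#'
#' @slot aggregator `"fisher"`, `"sumstat"`, `"bonferroni"` or `"single-set"`.
#' @slot statistic the observed aggregate statistic `T` (for Bonferroni, the
#'   minimum per-subset p-value).
#' @slot p.value permutation p-value of `T` on the grid
#'   `1/(P+1), ..., 1` (`NA` for Bonferroni, which yields a decision rule).
#' @slot chisq.p for Fisher's method only, the secondary chi-square reference
#'   p-value of `T` on `2m` degrees of freedom; `NA` otherwise.
#' @slot subset.p named per-subset permutation p-values \eqn{p_1 \ldots p_m}.
#' @slot subset.stat named observed per-subset statistics \eqn{t_1 \ldots t_m}.
#' @slot threshold Bonferroni cutoff `alpha/m` (`NA` otherwise).
#' @slot significant decision at level `alpha`.
#' @slot statisticName single-set statistic used (`"vc"`, `"vc2"`, `"burden"`).
#' @slot m,P,seed,alpha run parameters.
#' @export
setClass("MultisetResult",
    representation(aggregator = "character", statistic = "numeric",
                   p.value = "numeric", chisq.p = "numeric",
                   subset.p = "numeric", subset.stat = "numeric",
                   threshold = "numeric", significant = "logical",
                   statisticName = "character", m = "integer",
                   P = "integer", seed = "integer", alpha = "numeric"))

#' ScenarioConfig: parameters of a simulated case-control study
#'
#' Describes one cell of the factorial simulation design: `l` independent
#' rare variants for `nCases + nControls` individuals, a set of causal
#' variants carrying a per-allele relative risk `rr`, a law for population
#' minor-allele frequencies, and a partition of the variants into subsets.
#'
#' @slot l integer, total number of variants.
#' @slot nCases,nControls integer sample sizes.
#' @slot causal integer indices (into `1:l`) of the causal variants.
#' @slot rr per-allele relative risk for causal variants (1 = null).
#' @slot mafLaw list describing the population MAF distribution: either
#'   `list(dist = "uniform", min =, max =)` or `list(dist = "fixed",
#'   values =)` with `l` frequencies.
#' @slot partition factor of length `l` assigning variants to subsets.
#' @slot scenario label: `"1"`, `"2"`, `"3"`, `"4"` or `"custom"`.
#' @export
setClass("ScenarioConfig",
    representation(l = "integer", nCases = "integer", nControls = "integer",
                   causal = "integer", rr = "numeric", mafLaw = "list",
                   partition = "factor", scenario = "character"))

setValidity("ScenarioConfig", function(object) {
    msg <- NULL
    if (object@l < 1L) msg <- c(msg, "l must be >= 1")
    if (object@nCases < 1L || object@nControls < 1L)
        msg <- c(msg, "need at least one case and one control")
    if (length(object@causal) &&
        (min(object@causal) < 1L || max(object@causal) > object@l))
        msg <- c(msg, "causal indices must lie in 1..l")
    if (anyDuplicated(object@causal))
        msg <- c(msg, "causal indices must be unique")
    if (object@rr <= 0) msg <- c(msg, "rr must be > 0")
    if (length(object@partition) != object@l)
        msg <- c(msg, "partition must assign every variant")
    if (anyNA(object@partition))
        msg <- c(msg, "partition must be exhaustive (no NA)")
    if (!all(levels(object@partition) %in% as.character(object@partition)))
        msg <- c(msg, "every subset must be non-empty")
    law <- object@mafLaw
    if (identical(law$dist, "uniform")) {
        if (law$min <= 0 || law$max >= 0.5 || law$min > law$max)
            msg <- c(msg, "uniform MAF law requires 0 < min <= max < 0.5")
    } else if (identical(law$dist, "fixed")) {
        if (length(law$values) != object@l ||
            any(law$values <= 0 | law$values >= 0.5))
            msg <- c(msg, "fixed MAF law needs l frequencies in (0, 0.5)")
    } else msg <- c(msg, "mafLaw$dist must be 'uniform' or 'fixed'")
    if (is.null(msg)) TRUE else msg
})

#' DosageMatrix: imputed genotype dosages with per-variant quality
#'
#' Expected alternate-allele dosages in `[0, 2]` (rows are variants, columns
#' samples), with optional per-variant imputation quality `r2` and an
#' optional externally supplied MAF (e.g. from the imputation panel).
#'
#' @slot values numeric matrix of dosages in `[0, 2]` or `NA`.
#' @slot r2 per-variant imputation R-squared in `[0, 1]` (`NA` if unknown).
#' @slot maf per-variant minor-allele frequency override (`NA` if unknown).
#' @export
setClass("DosageMatrix",
    representation(values = "matrix", r2 = "numeric", maf = "numeric"))

setValidity("DosageMatrix", function(object) {
    msg <- NULL
    v <- object@values
    bad <- which(!is.na(v) & (v < 0 | v > 2))
    if (length(bad)) {
        i <- arrayInd(bad[1L], dim(v))
        msg <- c(msg, sprintf(
            "dosage outside [0, 2] at variant '%s', sample '%s' (value %g)",
            rownames(v)[i[1L]] %||% i[1L], colnames(v)[i[2L]] %||% i[2L],
            v[bad[1L]]))
    }
    l <- nrow(v)
    if (length(object@r2) != l || length(object@maf) != l)
        msg <- c(msg, "r2 and maf must have one entry per variant")
    if (any(!is.na(object@r2) & (object@r2 < 0 | object@r2 > 1)))
        msg <- c(msg, "r2 must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

`%||%` <- function(a, b) if (is.null(a)) b else a
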