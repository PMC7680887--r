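#' Construct a GenotypeExperiment
#'
#' Bundles a minor-allele count matrix with a binary phenotype (and,
#' optionally, a variant partition) into the container all tests in this
#' package operate on.
#'
#' @param counts integer matrix of minor-allele counts in `{0, 1, 2}` with
#'   `NA` for missing genotypes. Variants are rows and samples are columns;
#'   dimnames supply variant and sample ids (defaults are generated).
#' @param status case/control labels, one per sample: a factor or character
#'   vector with values `"case"`/`"control"`, or a 0/1 vector (1 = case).
#' @param subsets optional assignment of variants to mutually exclusive,
#'   exhaustive subsets: a factor or character vector of length `nrow(counts)`,
#'   or a named vector keyed by variant id. `NULL` leaves the partition unset
#'   (tests then treat all variants as one set).
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' cnt <- matrix(c(0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L), nrow = 2,
#'               dimnames = list(c("v1", "v2"), paste0("s", 1:4)))
#' ge <- GenotypeExperiment(cnt, status = c(1, 1, 0, 0))
#' alleleFreq(ge, "case")
#' @export
GenotypeExperiment <- function(counts, status, subsets = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("v", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    status <- normalizeStatus(status, ncol(counts))
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(subsets)) {
        if (!is.null(names(subsets))) {
            miss <- setdiff(rownames(counts), names(subsets))
            if (length(miss))
                stop("no subset assigned for variant(s): ",
                     paste(miss, collapse = ", "))
            subsets <- subsets[rownames(counts)]
        }
        if (length(subsets) != nrow(counts))
            stop("'subsets' must assign every variant exactly once")
        if (!is.factor(subsets))
            subsets <- factor(subsets, levels = unique(as.character(subsets)))
        rd$subset <- droplevels(subsets)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(status = status,
                                       row.names = colnames(counts)),
        rowData = rd)
    new("GenotypeExperiment", se)
}

normalizeStatus <- function(status, n) {
    if (length(status) != n)
        stop("'status' must have one label per sample")
    if (is.numeric(status) || is.logical(status)) {
        if (!all(status %in% c(0, 1)))
            stop("numeric 'status' must be 0 (control) / 1 (case)")
        status <- ifelse(status == 1, "case", "control")
    }
    status <- factor(as.character(status), levels = c("control", "case"))
    if (anyNA(status))
        stop("'status' values must be 'case'/'control' (or 1/0)")
    status
}

#' Access the genotype count matrix
#'
#' @param x a [GenotypeExperiment-class].
#' @return integer matrix, variants in rows.
#' @export
#' @name genotypeCounts
setMethod("genotypeCounts", "GenotypeExperiment", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' Access the case/control labels
#'
#' @param x a [GenotypeExperiment-class].
#' @return factor with levels `control`, `case`, one per sample.
#' @export
#' @name caseControl
setMethod("caseControl", "GenotypeExperiment", function(x)
    SummarizedExperiment::colData(x)$status)

#' Access or replace the variant partition
#'
#' @param x a [GenotypeExperiment-class].
#' @param value a factor/character vector of subset labels (or `NULL` to
#'   unset), as in [GenotypeExperiment()].
#' @return `variantSubsets` returns the subset factor (or `NULL` when no
#'   partition is set).
#' @export
#' @name variantSubsets
setMethod("variantSubsets", "GenotypeExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if ("subset" %in% colnames(rd)) rd$subset else NULL
})

#' @export
#' @name variantSubsets
setReplaceMethod("variantSubsets", "GenotypeExperiment", function(x, value) {
    if (is.null(value)) {
        SummarizedExperiment::rowData(x)$subset <- NULL
        return(x)
    }
    if (!is.null(names(value)))
        value <- value[rownames(x)]
    if (length(value) != nrow(x))
        stop("'value' must assign every variant exactly once")
    if (!is.factor(value))
        value <- factor(value, levels = unique(as.character(value)))
    SummarizedExperiment::rowData(x)$subset <- droplevels(value)
    validObject(x)
    x
})

#' Number of cases / controls
#'
#' @param x a [GenotypeExperiment-class].
#' @return integer count.
#' @export
nCases <- function(x) sum(caseControl(x) == "case")

#' @rdname nCases
#' @export
nControls <- function(x) sum(caseControl(x) == "control")

#' @export
#' @describeIn GenotypeExperiment compact display.
#' @param object a `GenotypeExperiment`.
setMethod("show", "GenotypeExperiment", function(object) {
    cat(sprintf("GenotypeExperiment: %d variants x %d samples (%d cases, %d controls)\n",
                nrow(object), ncol(object), nCases(object), nControls(object)))
    part <- variantSubsets(object)
    if (is.null(part)) {
        cat("  partition: none (single set)\n")
    } else {
        cat(sprintf("  partition: %d subsets (sizes %s)\n", nlevels(part),
                    paste(utils::head(as.integer(table(part)), 8),
                          collapse = ", ")))
    }
    miss <- sum(is.na(genotypeCounts(object)))
    if (miss > 0)
        cat(sprintf("  missing genotypes: %d\n", miss))
})

#' Orient counts to the minor allele
#'
#' Flips any variant whose overall (complete-case) alternate-allele frequency
#' exceeds 0.5, replacing counts `g` by `2 - g`, so that all variants count
#' the minor allele. Input data coded from VCF alternate alleles may need
#' this pre-pass; data already filtered to low MAF do not.
#'
#' @param x a [GenotypeExperiment-class] or a counts matrix (variants in rows).
#' @return the same type of object, with an attribute/metadata element
#'   `flipped` listing the variant ids that were recoded.
#' @export
orientMinorAllele <- function(x) {
    cnt <- if (is(x, "GenotypeExperiment")) genotypeCounts(x) else x
    freq <- rowSums(cnt, na.rm = TRUE) / (2 * rowSums(!is.na(cnt)))
    flip <- which(freq > 0.5)
    if (length(flip))
        cnt[flip, ] <- 2L - cnt[flip, ]
    if (is(x, "GenotypeExperiment")) {
        SummarizedExperiment::assay(x, "counts") <- cnt
        S4Vectors::metadata(x)$flipped <- rownames(cnt)[flip]
        x
    } else {
        attr(cnt, "flipped") <- rownames(cnt)[flip]
        cnt
    }
}
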