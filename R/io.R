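## File I/O: genotype matrices, VCF, SetID subset definitions, phenotypes,
## results TSV, and hard-calling of imputed dosages.

#' Read a delimited genotype matrix
#'
#' Reads a tab-delimited samples-by-variants table (header row of variant
#' ids, first column of sample ids; empty cells or `NA` for missing) and
#' returns it variants-by-samples, the orientation used throughout the
#' package.
#'
#' @param path file path.
#' @return integer matrix, variants in rows, samples in columns.
#' @seealso [writeGenotypeMatrix()] for the inverse.
#' @export
readGenotypeMatrix <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1L, check.names = FALSE,
                             colClasses = "character")
    m <- t(as.matrix(tab))
    suppressWarnings(storage.mode(m) <- "integer")
    bad <- which(!is.na(m) & !(m %in% 0:2))
    if (length(bad))
        stop("genotype entries must be 0, 1, 2 or missing (file ", path, ")")
    m
}

#' Write a genotype matrix
#'
#' Writes counts as a tab-delimited samples-by-variants table readable by
#' [readGenotypeMatrix()] (exact round trip).
#'
#' @param x a [GenotypeExperiment-class] or a variants-by-samples matrix.
#' @param path file path.
#' @export
writeGenotypeMatrix <- function(x, path) {
    cnt <- if (is(x, "GenotypeExperiment")) genotypeCounts(x) else x
    tab <- t(cnt)
    utils::write.table(
        data.frame(sample_id = rownames(tab), tab, check.names = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read genotypes or dosages from a VCF
#'
#' Parses a VCF 4.x file with `vcfR` and extracts either hard genotype
#' calls (`GT`: `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./. -> NA`; phased
#' separators accepted) or expected dosages (`DS`). Counts are oriented to
#' the alternate allele; run [orientMinorAllele()] afterwards if the data
#' are not already minor-allele coded. Multi-allelic records are rejected.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param field `"GT"` for hard calls (returns an integer matrix,
#'   variants x samples) or `"DS"` for dosages (returns a
#'   [DosageMatrix-class]; per-variant `R2` is taken from the INFO field
#'   when present, else `NA`).
#' @return integer matrix or [DosageMatrix-class]; variant ids come from
#'   the ID column, falling back to `chrom_pos_ref_alt`.
#' @export
readGenotypesVCF <- function(path, field = c("GT", "DS")) {
    field <- match.arg(field)
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf@fix
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt, fixed = TRUE)
    if (any(multi))
        stop("multi-allelic record(s) not supported; split them first: ",
             paste(utils::head(paste0(fix[multi, "CHROM"], ":",
                                      fix[multi, "POS"]), 5),
                   collapse = ", "))
    ids <- fix[, "ID"]
    fallback <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], alt,
                      sep = "_")
    ids <- ifelse(is.na(ids) | ids == ".", fallback, ids)
    if (anyDuplicated(ids))
        stop("duplicate variant ids in VCF")
    if (field == "GT") {
        gt <- vcfR::extract.gt(vcf, element = "GT")
        rownames(gt) <- ids
        code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
                  "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
        cnt <- matrix(code[gt], nrow = nrow(gt), dimnames = dimnames(gt))
        unparsed <- !is.na(gt) & gt != "./." & gt != ".|." & gt != "." &
            is.na(cnt)
        if (any(unparsed)) {
            i <- which(unparsed)[1L]
            stop("unparseable GT value '", gt[i], "' at variant ",
                 rownames(gt)[arrayInd(i, dim(gt))[1L]])
        }
        cnt
    } else {
        ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
        rownames(ds) <- ids
        r2 <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "R2")))
        if (length(r2) != nrow(ds)) r2 <- rep(NA_real_, nrow(ds))
        new("DosageMatrix", values = ds, r2 = r2,
            maf = rep(NA_real_, nrow(ds)))
    }
}

#' Read a SetID subset-definition file
#'
#' Reads the two-column SetID dialect used by SKAT-family tools
#' (`set_id  variant_id`, whitespace separated, no header) into a variant
#' partition. A variant listed under two sets violates mutual exclusivity
#' and is an error. When `variantIds` is supplied, the partition is
#' validated for exhaustiveness against it: unassigned variants are an
#' error unless `remainder = TRUE`, which collects them into a
#' `"REMAINDER"` subset; set entries for variants not in `variantIds`
#' are an error.
#'
#' @param path file path.
#' @param variantIds optional character vector of variant ids (e.g.
#'   `rownames` of the genotype matrix) to align and validate against.
#' @param remainder collect unassigned variants into a `REMAINDER` subset
#'   instead of failing.
#' @return a factor of subset labels (levels in order of first appearance),
#'   named by variant id; aligned to `variantIds` when given.
#' @export
readSubsets <- function(path, variantIds = NULL, remainder = FALSE) {
    tab <- utils::read.table(path, header = FALSE, col.names = c("set", "variant"),
                             colClasses = "character")
    if (nrow(tab) == 0L)
        stop("empty SetID file: ", path)
    dup <- unique(tab$variant[duplicated(tab$variant)])
    if (length(dup))
        stop("variant(s) assigned to more than one set: ",
             paste(utils::head(dup, 5), collapse = ", "))
    part <- factor(tab$set, levels = unique(tab$set))
    names(part) <- tab$variant
    if (is.null(variantIds))
        return(part)
    unknown <- setdiff(tab$variant, variantIds)
    if (length(unknown))
        stop("SetID file references variant(s) absent from the genotypes: ",
             paste(utils::head(unknown, 5), collapse = ", "))
    miss <- setdiff(variantIds, tab$variant)
    if (length(miss) && !remainder)
        stop(length(miss), " variant(s) not assigned to any set ",
             "(use remainder = TRUE to pool them): ",
             paste(utils::head(miss, 5), collapse = ", "))
    lev <- c(levels(part), if (length(miss)) "REMAINDER")
    out <- factor(stats::setNames(rep("REMAINDER", length(variantIds)),
                                  variantIds), levels = lev)
    out[names(part)[names(part) %in% variantIds]] <-
        as.character(part[names(part) %in% variantIds])
    names(out) <- variantIds
    droplevels(out)
}

#' Read a phenotype file
#'
#' Reads a two-column table of `sample_id` and case/control status (`1` =
#' case, `0` = control; a header line is detected and skipped). When
#' `sampleIds` is supplied the labels are matched by id and reordered;
#' unmatched ids in either direction are an error.
#'
#' @param path file path.
#' @param sampleIds optional sample ids to align against.
#' @return named factor with levels `control`, `case`.
#' @export
readPhenotype <- function(path, sampleIds = NULL) {
    first <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1L]]
    hasHeader <- length(first) >= 2L && !first[2L] %in% c("0", "1")
    tab <- utils::read.table(path, header = hasHeader,
                             col.names = c("sample", "status"),
                             colClasses = c("character", "character"))
    if (!all(tab$status %in% c("0", "1")))
        stop("phenotype status must be 0 (control) or 1 (case)")
    if (anyDuplicated(tab$sample))
        stop("duplicate sample id(s) in phenotype file")
    y <- normalizeStatus(as.integer(tab$status), nrow(tab))
    names(y) <- tab$sample
    if (!is.null(sampleIds)) {
        miss <- setdiff(sampleIds, tab$sample)
        if (length(miss))
            stop("no phenotype for sample(s): ",
                 paste(utils::head(miss, 5), collapse = ", "))
        extra <- setdiff(tab$sample, sampleIds)
        if (length(extra))
            stop("phenotype file has unknown sample(s): ",
                 paste(utils::head(extra, 5), collapse = ", "))
        y <- y[sampleIds]
    }
    y
}

#' Write test results as a TSV
#'
#' Serialises one or more [MultisetResult-class] objects (or the
#' data.frame from [powerStudy()]) to a tab-separated file. Result rows
#' embed `m`, `P`, `seed`, `alpha` and the package version, so a run is
#' reproducible from its output alone.
#'
#' @param results a `MultisetResult`, a list of them, or a data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeResults <- function(results, path) {
    if (is(results, "MultisetResult"))
        results <- list(results)
    if (is.list(results) && !is.data.frame(results))
        results <- do.call(rbind, lapply(results, as.data.frame))
    results$version <- as.character(utils::packageVersion("multisetRV"))
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Hard-call and filter imputed dosages
#'
#' Converts expected dosages to genotype calls and applies the
#' post-imputation quality filters: dosages strictly inside `(0.2, 0.8)`
#' or `(1.2, 1.8)` are set to missing (interval endpoints are kept) and
#' the remainder rounded to the nearest of 0/1/2; variants are then
#' dropped unless `MAF < mafMax` (strict) and `R2 > r2Min` (strict, so
#' `R2 = 0.4` is dropped at the default cutoff). MAF is computed from the
#' hardened calls over all samples (complete-case) unless
#' `useStoredMAF = TRUE`, which uses the `maf` slot (e.g. panel MAF)
#' instead.
#'
#' @param d a [DosageMatrix-class].
#' @param mafMax MAF cutoff (default 0.05); `NULL` skips the MAF filter.
#' @param r2Min imputation-quality cutoff (default 0.4); `NULL` skips the
#'   R2 filter. Variants with missing `R2` fail the filter.
#' @param useStoredMAF filter on `d@maf` instead of the sample MAF.
#' @return integer matrix of hardened calls for the retained variants,
#'   with attributes `nMasked` (dosages set to missing), `droppedMAF` and
#'   `droppedR2` (variant ids removed by each filter).
#' @examples
#' d <- new("DosageMatrix",
#'          values = matrix(c(0.1, 0.5, 1.2, 1.9), 2, 2,
#'                          dimnames = list(c("v1", "v2"), c("s1", "s2"))),
#'          r2 = c(0.9, 0.9), maf = c(NA_real_, NA_real_))
#' filterImputedDosages(d)
#' @export
filterImputedDosages <- function(d, mafMax = 0.05, r2Min = 0.4,
                                 useStoredMAF = FALSE) {
    stopifnot(is(d, "DosageMatrix"))
    validObject(d)
    v <- d@values
    mask <- !is.na(v) & ((v > 0.2 & v < 0.8) | (v > 1.2 & v < 1.8))
    v[mask] <- NA_real_
    cnt <- round(v)
    storage.mode(cnt) <- "integer"

    keep <- rep(TRUE, nrow(cnt))
    droppedR2 <- character(0)
    if (!is.null(r2Min)) {
        passR2 <- !is.na(d@r2) & d@r2 > r2Min
        droppedR2 <- rownames(cnt)[!passR2]
        keep <- keep & passR2
    }
    droppedMAF <- character(0)
    if (!is.null(mafMax)) {
        if (useStoredMAF) {
            maf <- d@maf
        } else {
            p <- rowSums(cnt, na.rm = TRUE) / (2 * rowSums(!is.na(cnt)))
            maf <- pmin(p, 1 - p)
        }
        passMAF <- !is.na(maf) & maf < mafMax
        droppedMAF <- rownames(cnt)[keep & !passMAF]
        keep <- keep & passMAF
    }
    out <- cnt[keep, , drop = FALSE]
    attr(out, "nMasked") <- sum(mask)
    attr(out, "droppedMAF") <- droppedMAF
    attr(out, "droppedR2") <- droppedR2
    message(sprintf(
        "dosage filter: %d variants in, %d dropped by R2, %d by MAF, %d kept; %d dosages masked",
        nrow(cnt), length(droppedR2), length(droppedMAF), nrow(out),
        sum(mask)))
    out
}

#' @describeIn filterImputedDosages display method for dosage matrices.
#' @param object a `DosageMatrix`.
#' @export
setMethod("show", "DosageMatrix", function(object) {
    cat(sprintf("DosageMatrix: %d variants x %d samples; R2 known for %d variants\n",
                nrow(object@values), ncol(object@values),
                sum(!is.na(object@r2))))
    invisible(object)
})
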