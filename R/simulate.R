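## Case-control genotype simulator and factorial power-study harness.
##
## Disease model: each variant h has a population minor-allele frequency
## f_h drawn once per dataset from the configured MAF law. Controls carry
## Binomial(2, f_h) genotypes (Hardy-Weinberg). Causal variants are
## enriched in cases by a per-allele relative risk rr under retrospective
## sampling: the case allele frequency is f rr / (f rr + 1 - f), with
## controls at the population frequency (rare-disease approximation).
## Variants are independent (no linkage disequilibrium).

#' Case allele frequency under a per-allele relative risk
#'
#' Retrospective-sampling enrichment of a causal allele in cases:
#' \deqn{f^+ = \frac{f \cdot rr}{f \cdot rr + (1 - f)}.}
#' At `rr = 1` this is the population frequency; as `f` tends to 0 the
#' enrichment ratio `f+/f` tends to `rr`.
#'
#' @param f population minor-allele frequency/frequencies in `(0, 1)`.
#' @param rr per-allele relative risk, `> 0`.
#' @return case allele frequency, same length as `f`.
#' @examples
#' caseAlleleFrequency(0.005, 1.15)  # ~ 0.005746
#' @export
caseAlleleFrequency <- function(f, rr) {
    stopifnot(all(f > 0 & f < 1), rr > 0)
    f * rr / (f * rr + (1 - f))
}

#' Build a simulation scenario configuration
#'
#' Constructs one cell of the 2x2 factorial simulation design crossing
#' equal/unequal subset sizes with equal/unequal proportions of causal
#' variants per subset. Defaults reproduce the study conditions: `l = 1024`
#' variants, 500 cases and 500 controls, 128 causal variants (12.5%) with
#' per-allele relative risk 1.15. Setting `rr = 1` gives the null (type-I
#' error) configuration.
#'
#' @param scenario 1, 2, 3 or 4:
#'   * **1** — `m` equal subsets of `l/m` variants, each holding the same
#'     proportion (`nCausal/l`) of causal variants; `m` must divide both
#'     `l` and `nCausal`.
#'   * **2** — two subsets of unequal size (`smallSize` and the remainder),
#'     causal proportion `nCausal/l` maintained within each.
#'   * **3** — `m` equal subsets; all causal variants concentrated
#'     uniformly in the first `causalFractionSets * m` subsets.
#'   * **4** — two unequal subsets; `causalInSmall` of the causal variants
#'     in the smaller subset, the rest in the larger.
#' @param m number of subsets (scenarios 1 and 3).
#' @param smallSize number of variants in the smaller of the two subsets
#'   (scenarios 2 and 4).
#' @param causalFractionSets fraction of the subsets that jointly contain
#'   all causal variants (scenario 3), e.g. 1/8, 1/4, 1/2, 3/4.
#' @param causalInSmall how many causal variants go to the smaller subset
#'   (scenario 4).
#' @param l,nCases,nControls,nCausal,rr study dimensions and effect size.
#' @param mafLaw population MAF distribution; default
#'   `list(dist = "uniform", min = 0.001, max = 0.01)`, i.i.d. uniform on a
#'   rare-variant range. A `list(dist = "fixed", values = ...)` law pins
#'   exact frequencies.
#' @return a [ScenarioConfig-class].
#' @examples
#' makeScenario(1, m = 8)                        # 8 x 128 variants, 16 causal each
#' makeScenario(3, m = 8, causalFractionSets = 1/8)  # one fully causal subset
#' @export
makeScenario <- function(scenario, m = NULL, smallSize = NULL,
                         causalFractionSets = NULL, causalInSmall = NULL,
                         l = 1024L, nCases = 500L, nControls = 500L,
                         nCausal = 128L, rr = 1.15,
                         mafLaw = list(dist = "uniform",
                                       min = 0.001, max = 0.01)) {
    scenario <- as.character(scenario)
    l <- as.integer(l); nCausal <- as.integer(nCausal)
    if (nCausal > l) stop("nCausal cannot exceed l")
    blockPartition <- function(m) {
        if (l %% m != 0L)
            stop("m = ", m, " does not divide l = ", l)
        factor(rep(paste0("set", seq_len(m)), each = l %/% m),
               levels = paste0("set", seq_len(m)))
    }
    if (scenario == "1") {
        if (is.null(m)) stop("scenario 1 requires m")
        m <- as.integer(m)
        part <- blockPartition(m)
        if (nCausal %% m != 0L)
            stop("m = ", m, " does not divide nCausal = ", nCausal,
                 "; equal causal proportions are impossible")
        block <- l %/% m; cpb <- nCausal %/% m
        causal <- as.integer(outer(seq_len(cpb), (seq_len(m) - 1L) * block, "+"))
    } else if (scenario == "2") {
        if (is.null(smallSize)) stop("scenario 2 requires smallSize")
        k <- as.integer(smallSize)
        if (k < 1L || k > l %/% 2L)
            stop("smallSize must lie in 1..l/2")
        cs <- k * nCausal / l
        if (cs != round(cs))
            stop("smallSize = ", k, " cannot hold causal proportion ",
                 nCausal, "/", l, " exactly")
        cs <- as.integer(cs)
        part <- factor(rep(c("set1", "set2"), c(k, l - k)),
                       levels = c("set1", "set2"))
        causal <- c(seq_len(cs), k + seq_len(nCausal - cs))
    } else if (scenario == "3") {
        if (is.null(m) || is.null(causalFractionSets))
            stop("scenario 3 requires m and causalFractionSets")
        m <- as.integer(m)
        part <- blockPartition(m)
        ncs <- causalFractionSets * m
        if (abs(ncs - round(ncs)) > 1e-8 || round(ncs) < 1)
            stop("causalFractionSets * m must be a positive integer")
        ncs <- as.integer(round(ncs))
        if (nCausal %% ncs != 0L)
            stop("cannot spread ", nCausal, " causal variants uniformly ",
                 "over ", ncs, " subsets")
        cps <- nCausal %/% ncs
        if (cps > l %/% m)
            stop("causal variants per subset (", cps, ") exceed subset size")
        block <- l %/% m
        causal <- as.integer(outer(seq_len(cps), (seq_len(ncs) - 1L) * block, "+"))
    } else if (scenario == "4") {
        if (is.null(smallSize) || is.null(causalInSmall))
            stop("scenario 4 requires smallSize and causalInSmall")
        k <- as.integer(smallSize); cs <- as.integer(causalInSmall)
        if (k < 1L || k >= l) stop("smallSize must lie in 1..l-1")
        if (cs < 0L || cs > min(k, nCausal))
            stop("causalInSmall must lie in 0..min(smallSize, nCausal)")
        if (nCausal - cs > l - k)
            stop("larger subset cannot hold the remaining causal variants")
        part <- factor(rep(c("set1", "set2"), c(k, l - k)),
                       levels = c("set1", "set2"))
        causal <- c(seq_len(cs), k + seq_len(nCausal - cs))
    } else stop("scenario must be 1, 2, 3 or 4 (use ScenarioConfig for custom)")
    new("ScenarioConfig", l = l, nCases = as.integer(nCases),
        nControls = as.integer(nControls), causal = as.integer(causal),
        rr = rr, mafLaw = mafLaw, partition = part, scenario = scenario)
}

## One dataset from the current RNG stream (no reseeding).
.simulateCounts <- function(cfg) {
    l <- cfg@l
    f <- switch(cfg@mafLaw$dist,
        uniform = stats::runif(l, cfg@mafLaw$min, cfg@mafLaw$max),
        fixed = cfg@mafLaw$values)
    fCase <- f
    if (length(cfg@causal))
        fCase[cfg@causal] <- caseAlleleFrequency(f[cfg@causal], cfg@rr)
    caseM <- matrix(stats::rbinom(l * cfg@nCases, 2L, fCase), nrow = l)
    ctrlM <- matrix(stats::rbinom(l * cfg@nControls, 2L, f), nrow = l)
    counts <- cbind(caseM, ctrlM)
    rownames(counts) <- paste0("v", seq_len(l))
    colnames(counts) <- c(paste0("case", seq_len(cfg@nCases)),
                          paste0("ctrl", seq_len(cfg@nControls)))
    status <- factor(rep(c("case", "control"), c(cfg@nCases, cfg@nControls)),
                     levels = c("control", "case"))
    list(counts = counts, status = status)
}

#' Simulate a case-control genotype dataset
#'
#' Draws population MAFs from the scenario's MAF law, enriches causal
#' variants in cases by the configured relative risk (see
#' [caseAlleleFrequency()]), and samples independent Hardy-Weinberg
#' `Binomial(2, f)` genotypes. Fully reproducible from the seed.
#'
#' @param cfg a [ScenarioConfig-class], e.g. from [makeScenario()].
#' @param seed integer RNG seed.
#' @return a [GenotypeExperiment-class] carrying the scenario's partition.
#' @export
simulateDataset <- function(cfg, seed = 1L) {
    validObject(cfg)
    set.seed(seed)
    sim <- .simulateCounts(cfg)
    GenotypeExperiment(sim$counts, sim$status, subsets = cfg@partition)
}

#' Monte-Carlo margin of error of a power estimate
#'
#' Normal-approximation 95% half-width of a rejection proportion,
#' \eqn{1.96\sqrt{\hat p (1-\hat p)/n_{sim}}}, reported as a percentage.
#'
#' @param pHat estimated proportion(s) in `[0, 1]`.
#' @param nsim number of simulation replicates.
#' @return half-width in percent (e.g. `1.35` for `pHat = 0.05`,
#'   `nsim = 1000`).
#' @export
marginOfError <- function(pHat, nsim) {
    stopifnot(all(pHat >= 0 & pHat <= 1), nsim >= 1)
    100 * 1.96 * sqrt(pHat * (1 - pHat) / nsim)
}

#' Estimate power (or type-I error) by simulation
#'
#' `powerStudy()` simulates `nsim` datasets from a scenario and, on each,
#' runs the single-set test and the multi-set test under the requested
#' aggregators for one or several partitions, sharing the simulated data
#' and the permutation pool across all methods (common random numbers).
#' `estimatePower()` is the single-partition convenience wrapper using the
#' partition stored in the scenario.
#'
#' Rejection is `p <= alpha` for the permutation-based methods and the
#' strict Bonferroni rule `min(p) < alpha/m` for `"bonferroni"`. With
#' `rr = 1` in the scenario the rejection proportion estimates the type-I
#' error.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param partitions named list of partitions (factors of length `cfg@l`)
#'   to evaluate; `NULL` uses the scenario's own partition under the name
#'   `"multiset"`.
#' @param aggregators subset of `c("single", "fisher", "sumstat",
#'   "bonferroni")` (`"single"` is the single-set test and ignores the
#'   partitions).
#' @param nsim number of simulated datasets.
#' @param alpha significance level.
#' @param P permutations per dataset (default 199; p-value resolution
#'   `1/(P+1) = 0.005` suffices for decisions at `alpha = 0.05`).
#' @param stat single-set statistic, as in [multisetTest()].
#' @param seed master seed; each replicate runs from an independently drawn
#'   sub-seed so replicates are individually reproducible.
#' @return a tidy `data.frame` with one row per (partition, aggregator):
#'   columns `scenario`, `partition`, `m`, `aggregator`, `stat`, `rr`,
#'   `nsim`, `alpha`, `P`, `seed`, `power`, `moe` (percent).
#' @examples
#' cfg <- makeScenario(1, m = 4, l = 64, nCausal = 8, nCases = 50,
#'                     nControls = 50, rr = 1)
#' estimatePower(cfg, nsim = 20, P = 49, seed = 1)  # null: power ~ alpha
#' @export
powerStudy <- function(cfg, partitions = NULL,
                       aggregators = c("single", "fisher", "sumstat",
                                       "bonferroni"),
                       nsim = 1000L, alpha = 0.05, P = 199L,
                       stat = c("vc", "vc2", "burden"), seed = 1L) {
    validObject(cfg)
    stat <- match.arg(stat)
    aggregators <- match.arg(aggregators, several.ok = TRUE)
    if (is.null(partitions))
        partitions <- list(multiset = cfg@partition)
    if (is.null(names(partitions)))
        names(partitions) <- paste0("partition", seq_along(partitions))
    for (p in partitions)
        if (length(p) != cfg@l)
            stop("every partition must assign all ", cfg@l, " variants")
    partitions <- lapply(partitions, function(p)
        droplevels(if (is.factor(p)) p else factor(p)))
    multi <- setdiff(aggregators, "single")
    N <- cfg@nCases + cfg@nControls
    singlePart <- factor(rep("all", cfg@l))

    set.seed(seed)
    repSeeds <- sample.int(2147483646L, nsim)
    cells <- c(if ("single" %in% aggregators) "single",
               if (length(multi)) as.vector(outer(multi, names(partitions),
                                                  paste, sep = "\r")))
    rejections <- stats::setNames(numeric(length(cells)), cells)

    for (r in seq_len(nsim)) {
        set.seed(repSeeds[r])
        sim <- .simulateCounts(cfg)
        perms <- vapply(seq_len(P), function(k) sample.int(N), integer(N))
        Z <- .indicatorMatrix(sim$status, perms)
        delta <- .freqDeltaPool(sim$counts, Z)
        if ("single" %in% aggregators) {
            S1 <- .subsetStatPool(delta, singlePart, stat)
            res <- .aggregateS(S1, "single-set", alpha, P)
            rejections["single"] <- rejections["single"] + res$significant
        }
        for (pn in names(partitions)) {
            Sp <- .subsetStatPool(delta, partitions[[pn]], stat)
            for (agg in multi) {
                res <- .aggregateS(Sp, agg, alpha, P)
                key <- paste(agg, pn, sep = "\r")
                rejections[key] <- rejections[key] + res$significant
            }
        }
    }

    rows <- lapply(cells, function(cell) {
        if (cell == "single") {
            agg <- "single"; pn <- NA_character_; m <- 1L
        } else {
            bits <- strsplit(cell, "\r", fixed = TRUE)[[1L]]
            agg <- bits[1L]; pn <- bits[2L]
            m <- nlevels(partitions[[pn]])
        }
        pw <- rejections[[cell]] / nsim
        data.frame(scenario = cfg@scenario, partition = pn, m = m,
                   aggregator = agg, stat = stat, rr = cfg@rr,
                   nsim = as.integer(nsim), alpha = alpha,
                   P = as.integer(P), seed = as.integer(seed),
                   power = pw, moe = marginOfError(pw, nsim),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' @rdname powerStudy
#' @param ... passed through to `powerStudy()`.
#' @export
estimatePower <- function(cfg, ...) powerStudy(cfg, partitions = NULL, ...)

#' @describeIn makeScenario display method.
#' @param object a `ScenarioConfig`.
#' @export
setMethod("show", "ScenarioConfig", function(object) {
    sizes <- as.integer(table(object@partition))
    cat(sprintf("ScenarioConfig (scenario %s): l = %d variants, %d cases / %d controls\n",
                object@scenario, object@l, object@nCases, object@nControls))
    cat(sprintf("  %d causal variants, rr = %g; %d subsets (sizes %s%s)\n",
                length(object@causal), object@rr, nlevels(object@partition),
                paste(utils::head(sizes, 8), collapse = ", "),
                if (length(sizes) > 8) ", ..." else ""))
    law <- object@mafLaw
    if (identical(law$dist, "uniform"))
        cat(sprintf("  MAF ~ Uniform(%g, %g)\n", law$min, law$max))
    else
        cat("  MAF: fixed per-variant frequencies\n")
    invisible(object)
})
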