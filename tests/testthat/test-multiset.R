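# Multi-set engine: permutations, pools, per-subset p-values, aggregation.

test_that("label permutations conserve group sizes and are seed-reproducible", {
    y <- factor(rep(c("case", "control"), c(7, 13)),
                levels = c("control", "case"))
    labs <- permuteLabels(y, P = 25, seed = 5)
    expect_length(labs, 25)
    for (lab in labs)
        expect_equal(sum(lab == "case"), 7)
    expect_identical(labs, permuteLabels(y, P = 25, seed = 5))
    expect_false(identical(labs, permuteLabels(y, P = 25, seed = 6)))
})

test_that("a single permutation of two labels visits both arrangements", {
    y <- factor(c("case", "control"), levels = c("control", "case"))
    first <- vapply(1:200, function(sd)
        as.character(permuteLabels(y, P = 1, seed = sd)[[1]][1]),
        character(1))
    tab <- table(first)
    expect_setequal(names(tab), c("case", "control"))
    expect_gt(min(tab), 60)  # each arrangement has probability 1/2 over seeds
})

test_that("permutation pool matches brute-force recomputation on a toy", {
    toy <- randomToy(101, N = 6, l = 4)
    part <- factor(rep(c("A", "B"), each = 2))
    for (stat in c("vc", "vc2", "burden")) {
        pool <- buildPermutationPool(toy$ge, stat = stat, P = 20, seed = 9,
                                     subsets = part)
        ref <- naivePool(toy$counts, toy$status, part, stat, 20, 9)
        expect_equal(unname(pool@observed), unname(ref$observed))
        expect_equal(unname(pool@permuted), unname(ref$permuted))
    }
})

test_that("one-subset pools equal the single-set statistic per permutation", {
    toy <- randomToy(102, N = 8, l = 5)
    pool <- buildPermutationPool(toy$ge, P = 15, seed = 3)
    labs <- permuteLabels(toy$status, 15, 3)
    expect_equal(unname(pool@observed), naiveStat(toy$counts, toy$status))
    for (k in 1:15)
        expect_equal(unname(pool@permuted[k, 1]),
                     naiveStat(toy$counts, labs[[k]]))
})

test_that("an all-zero subset contributes identically zero statistics", {
    cnt <- rbind(v1 = c(1L, 0L, 0L, 1L, 0L, 0L), v2 = rep(0L, 6),
                 v3 = rep(0L, 6))
    ge <- GenotypeExperiment(cnt, c(1, 1, 1, 0, 0, 0))
    pool <- buildPermutationPool(ge, P = 10, seed = 1,
                                 subsets = c(v1 = "A", v2 = "B", v3 = "B"))
    expect_equal(unname(pool@observed["B"]), 0)
    expect_equal(unname(pool@permuted[, 2]), rep(0, 10))
})

test_that("pool p-values follow the add-one, ties-as-extreme rank rule", {
    mk <- function(t, s) new("PermutationPool", observed = c(x = t),
                             permuted = matrix(s, ncol = 1),
                             P = length(s), statistic = "vc", seed = 1L)
    # t = 5 against s = (1, 2, 5, 7): one tie, one exceedance -> 3/5
    pv <- poolPValues(mk(5, c(1, 2, 5, 7)))
    expect_equal(unname(pv$observed), 0.6)
    expect_equal(unname(pv$permuted[, 1]), c(1, 0.8, 0.6, 0.2))

    # observed strictly above every permuted value -> 1/(P+1)
    expect_equal(unname(poolPValues(mk(9, 1:8))$observed), 1 / 9)

    # constant statistic -> p = 1 everywhere
    pvc <- poolPValues(mk(2, rep(2, 6)))
    expect_equal(unname(pvc$observed), 1)
    expect_equal(unname(pvc$permuted[, 1]), rep(1, 6))

    # matches the naive rank oracle on random columns
    set.seed(77)
    for (i in 1:10) {
        v <- round(rexp(12), 2)
        pv <- poolPValues(mk(v[1], v[-1]))
        ref <- naiveColP(v)
        expect_equal(unname(c(pv$observed, pv$permuted[, 1])), ref)
    }
})

test_that("multi-set test at m = 1 reduces exactly to the single-set test", {
    for (sd in 201:205) {
        toy <- randomToy(sd, N = 10, l = 5)
        one <- rep("all", 5)
        rf <- multisetTest(toy$ge, "fisher", P = 49, seed = sd, subsets = one)
        rs <- multisetTest(toy$ge, "sumstat", P = 49, seed = sd, subsets = one)
        ss <- singleSetTest(toy$ge, P = 49, seed = sd)
        expect_identical(rf@p.value, ss@p.value)
        expect_identical(rs@p.value, ss@p.value)
        expect_identical(rs@statistic, ss@statistic)
        # Bonferroni at m = 1 is the plain (strict) alpha test on p_1
        rb <- multisetTest(toy$ge, "bonferroni", P = 49, seed = sd,
                           subsets = one)
        expect_identical(rb@statistic, unname(ss@subset.p))
        expect_identical(rb@significant, rb@statistic < 0.05)
    }
})

test_that("SUMSTAT with the squared norm is partition-invariant", {
    for (sd in 301:308) {
        toy <- randomToy(sd, N = 12, l = 6)
        part <- sample(c("A", "B", "C"), 6, replace = TRUE)
        part[1:3] <- c("A", "B", "C")  # keep every subset non-empty
        rp <- multisetTest(toy$ge, "sumstat", stat = "vc2", P = 49,
                           seed = sd, subsets = part)
        ss <- singleSetTest(toy$ge, stat = "vc2", P = 49, seed = sd)
        expect_identical(rp@statistic, ss@statistic)
        expect_identical(rp@p.value, ss@p.value)
    }
})

test_that("engine results match full brute-force recomputation on toys", {
    for (sd in 401:404) {
        toy <- randomToy(sd, N = 10, l = 4)
        part <- factor(c("A", "A", "B", "B"))
        P <- 50
        ref <- naivePool(toy$counts, toy$status, part, "vc", P, sd)
        refP <- apply(rbind(ref$observed, ref$permuted), 2, naiveColP)
        # Fisher: T = -2 sum log p, compared to its permutation distribution
        Tall <- -2 * rowSums(log(refP))
        pFisher <- sum(Tall >= Tall[1]) / (P + 1)
        # SUMSTAT on the raw statistics
        Sall <- rowSums(rbind(ref$observed, ref$permuted))
        pSum <- sum(Sall >= Sall[1]) / (P + 1)
        rf <- multisetTest(toy$ge, "fisher", P = P, seed = sd, subsets = part)
        rs <- multisetTest(toy$ge, "sumstat", P = P, seed = sd, subsets = part)
        rb <- multisetTest(toy$ge, "bonferroni", P = P, seed = sd,
                           subsets = part)
        expect_equal(unname(rf@subset.p), unname(refP[1, ]))
        expect_equal(rf@p.value, pFisher)
        expect_equal(rs@p.value, pSum)
        expect_equal(rb@statistic, min(refP[1, ]))
        expect_equal(rb@threshold, 0.05 / 2)
    }
})

test_that("a clean case-only allele yields the minimum attainable p-value", {
    # every case carries an allele absent from all controls, P = 199
    cnt <- rbind(signal = rep(c(1L, 0L), each = 10),
                 noise = rep(c(0L, 1L, 0L, 0L), 5))
    colnames(cnt) <- paste0("s", 1:20)
    ge <- GenotypeExperiment(cnt, rep(c(1, 0), each = 10))
    res <- singleSetTest(ge, P = 199, seed = 11)
    expect_equal(res@p.value, 1 / 200)
})

test_that("identical inputs give bit-identical results", {
    toy <- randomToy(500, N = 10, l = 5)
    part <- factor(c("A", "A", "B", "B", "B"))
    r1 <- multisetTest(toy$ge, "fisher", P = 99, seed = 77, subsets = part)
    r2 <- multisetTest(toy$ge, "fisher", P = 99, seed = 77, subsets = part)
    expect_identical(r1, r2)
})

test_that("zero-variance genotypes give p = 1", {
    ge <- GenotypeExperiment(matrix(0L, 3, 8), rep(c(1, 0), 4))
    expect_equal(singleSetTest(ge, P = 49, seed = 1)@p.value, 1)
})

test_that("invalid partitions and aggregators are rejected", {
    toy <- randomToy(600, N = 6, l = 3)
    expect_error(multisetTest(toy$ge, "fisher", P = 9, seed = 1,
                              subsets = c(v1 = "A", v2 = "A", vX = "B")),
                 "unknown variant")
    expect_error(multisetTest(toy$ge, "fisher", P = 9, seed = 1,
                              subsets = c(v1 = "A", v2 = "A")),
                 "exhaustive|assign")
    expect_error(multisetTest(toy$ge, "stouffer"))
})

test_that("null p-values are uniform on their support", {
    set.seed(2024)
    nrep <- 400
    P <- 99
    pf <- ps <- numeric(nrep)
    for (r in 1:nrep) {
        cnt <- matrix(rbinom(8 * 24, 2, 0.1), nrow = 8)
        rownames(cnt) <- paste0("v", 1:8)
        ge <- GenotypeExperiment(cnt, rep(c(1, 0), 12))
        part <- factor(rep(c("A", "B"), each = 4))
        sd <- sample.int(1e6, 1)
        pf[r] <- multisetTest(ge, "fisher", P = P, seed = sd,
                              subsets = part)@p.value
        ps[r] <- multisetTest(ge, "sumstat", P = P, seed = sd,
                              subsets = part)@p.value
    }
    for (p in list(pf, ps)) {
        D <- max(abs(sort(p) - (seq_along(p) - 0.5) / length(p)))
        expect_lt(D, 0.09)  # coarse KS bound: ~1.36/sqrt(400) = 0.068
        # empirical size within 3 binomial SEs of alpha = 0.05
        expect_lt(abs(mean(p <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / nrep))
    }
})
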