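# Genotype simulator and power-study harness.

test_that("case allele frequency follows the retrospective enrichment form", {
    expect_equal(caseAlleleFrequency(0.02, 1), 0.02)       # null identity
    expect_equal(caseAlleleFrequency(0.005, 1.15), 0.00575 / 1.00075)
    # limiting enrichment f+ / f -> rr as f -> 0
    expect_equal(caseAlleleFrequency(1e-7, 1.15) / 1e-7, 1.15,
                 tolerance = 1e-4)
    expect_error(caseAlleleFrequency(0, 1.15))
    expect_error(caseAlleleFrequency(0.1, -1))
})

test_that("simulated case frequencies converge to the enriched frequency", {
    # 1e5 case chromosomes at a causal variant with fixed MAF
    cfg <- new("ScenarioConfig", l = 2L, nCases = 50000L, nControls = 10L,
               causal = 1L, rr = 1.5,
               mafLaw = list(dist = "fixed", values = c(0.01, 0.01)),
               partition = factor(c("A", "A")), scenario = "custom")
    ge <- simulateDataset(cfg, seed = 99)
    fplus <- caseAlleleFrequency(0.01, 1.5)
    fhat <- sum(genotypeCounts(ge)[1, caseControl(ge) == "case"]) / 1e5
    expect_lt(abs(fhat - fplus), 3 * sqrt(fplus * (1 - fplus) / 1e5))
    # non-causal variant stays at the population frequency
    fhat2 <- sum(genotypeCounts(ge)[2, caseControl(ge) == "case"]) / 1e5
    expect_lt(abs(fhat2 - 0.01), 3 * sqrt(0.01 * 0.99 / 1e5))
})

test_that("datasets are reproducible from the seed", {
    cfg <- makeScenario(1, m = 2, l = 32, nCausal = 4, nCases = 20,
                        nControls = 20, rr = 1.5)
    expect_identical(genotypeCounts(simulateDataset(cfg, seed = 5)),
                     genotypeCounts(simulateDataset(cfg, seed = 5)))
    expect_false(identical(genotypeCounts(simulateDataset(cfg, seed = 5)),
                           genotypeCounts(simulateDataset(cfg, seed = 6))))
})

test_that("scenario 1 spreads causal variants evenly over equal subsets", {
    cfg <- makeScenario(1, m = 8)
    expect_equal(as.integer(table(cfg@partition)), rep(128L, 8))
    perSet <- table(cfg@partition[cfg@causal])
    expect_equal(as.integer(perSet), rep(16L, 8))
    expect_error(makeScenario(1, m = 3), "does not divide")
    expect_error(makeScenario(1, m = 256), "does not divide")
})

test_that("scenario 2 keeps the causal proportion in unequal subsets", {
    cfg <- makeScenario(2, smallSize = 64)
    expect_equal(as.integer(table(cfg@partition)), c(64L, 960L))
    perSet <- table(cfg@partition[cfg@causal])
    expect_equal(as.integer(perSet), c(8L, 120L))  # 1/8 of each subset
    expect_error(makeScenario(2, smallSize = 10), "cannot hold")
})

test_that("scenario 3 concentrates all causal variants in a few subsets", {
    cfg <- makeScenario(3, m = 8, causalFractionSets = 1 / 8)
    perSet <- table(cfg@partition[cfg@causal])
    expect_equal(as.integer(perSet["set1"]), 128L)  # one fully causal subset
    expect_equal(sum(perSet), 128L)
    cfg4 <- makeScenario(3, m = 8, causalFractionSets = 1 / 2)
    expect_equal(as.integer(table(cfg4@partition[cfg4@causal])),
                 c(rep(32L, 4), rep(0L, 4)))
    expect_error(makeScenario(3, m = 8, causalFractionSets = 1 / 3),
                 "positive integer")
})

test_that("scenario 4 places none, some or all causal variants in the small set", {
    cfg <- makeScenario(4, smallSize = 128, causalInSmall = 128)
    expect_equal(sum(cfg@causal <= 128), 128L)  # smaller subset fully causal
    cfg0 <- makeScenario(4, smallSize = 128, causalInSmall = 0)
    expect_equal(sum(cfg0@causal <= 128), 0L)
    expect_error(makeScenario(4, smallSize = 64, causalInSmall = 100),
                 "causalInSmall")
    expect_error(makeScenario(4, smallSize = 1000, causalInSmall = 0),
                 "larger subset")
})

test_that("margin of error matches the 95% binomial half-width", {
    expect_equal(round(marginOfError(0.05, 1000), 1), 1.4)
    expect_lt(marginOfError(0.5, 1000), 3.5)
    expect_equal(marginOfError(0.5, 1000), 100 * 1.96 * sqrt(0.25 / 1000))
    expect_equal(marginOfError(c(0, 1), 1000), c(0, 0))
})

test_that("power estimation is exact at alpha = 1 and seed-reproducible", {
    cfg <- makeScenario(1, m = 2, l = 16, nCausal = 2, nCases = 15,
                        nControls = 15, rr = 1)
    ps <- estimatePower(cfg, aggregators = c("single", "fisher", "sumstat"),
                        nsim = 8, alpha = 1, P = 19, seed = 3)
    expect_true(all(ps$power == 1))
    ps1 <- estimatePower(cfg, nsim = 8, P = 19, seed = 3)
    ps2 <- estimatePower(cfg, nsim = 8, P = 19, seed = 3)
    expect_identical(ps1, ps2)
    expect_equal(ps1$moe, marginOfError(ps1$power, 8))
})

test_that("power is non-decreasing in the relative risk", {
    powers <- vapply(c(1, 1.3, 1.6), function(rr) {
        cfg <- shapeScenario(1, m = 2)
        cfg@rr <- rr
        ps <- powerStudy(cfg, aggregators = "single", nsim = 60, P = 99,
                         seed = 314)
        ps$power
    }, numeric(1))
    # allow Monte-Carlo error of ~2 SE at nsim = 60 on each step
    slack <- 2 * sqrt(0.25 / 60)
    expect_gt(powers[2], powers[1] - slack)
    expect_gt(powers[3], powers[2] - slack)
    expect_gt(powers[3], powers[1] + 0.2)  # clear overall gain
})

test_that("null rejection rates stay near alpha for every method", {
    cfg <- shapeScenario(1, m = 8)
    cfg@rr <- 1
    ps <- powerStudy(cfg, nsim = 150, P = 199, seed = 271)
    for (i in seq_len(nrow(ps)))
        expect_lt(ps$power[i], 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
})
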