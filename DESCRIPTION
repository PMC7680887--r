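Package: multisetRV
Title: Multi-Set Association Testing for Large Sets of Rare Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Set-based association testing for rare variants in case-control
    studies. Implements a simplified variance-component (SKAT-equivalent)
    statistic, the Euclidean distance between case and control allele-frequency
    vectors, with permutation-based p-values, and a multi-set ("pathway-style")
    strategy that partitions variants into mutually exclusive subsets, tests
    each subset, and aggregates the evidence with Fisher's method, SUMSTAT, or
    a Bonferroni min-p decision rule. Includes a case-control genotype
    simulator under a per-allele relative-risk disease model, a factorial
    power-study harness contrasting single-set and multi-set strategies, and
    readers for VCF, genotype-matrix, SetID and phenotype files, with
    hard-calling filters for imputed dosages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
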