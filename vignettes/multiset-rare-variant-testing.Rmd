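---
title: "Multi-set testing of rare variants: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-set testing of rare variants: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisetRV)
```

## The testing problem

Given minor-allele counts for $l$ rare single-nucleotide variants in $N$
individuals with a binary case/control phenotype, we want a single test of
the null hypothesis that none of the variants is associated with the
phenotype. Two strategies are compared throughout this package:

* **single-set**: one statistic on all $l$ variants;
* **multi-set**: partition the variants into $m$ mutually exclusive,
  exhaustive subsets, compute the statistic on each, and aggregate the $m$
  results into one set-level test.

The subset definition is the analyst's prior biology (genes of a pathway,
exons of a gene, windows). The package's purpose is to make both routes
available on the same data with identical permutation machinery so the
comparison is fair.

## The single-set statistic

For variant $h$, let $F^+_h$ be the minor-allele count among cases divided
by the number of case chromosomes at that variant, and $F^-_h$ the same for
controls. The variance-component statistic is

$$\mathrm{VC} = \lVert F^+ - F^- \rVert = \Big(\sum_{h=1}^{l} (F^+_h - F^-_h)^2\Big)^{1/2},$$

a simplified, monotone-equivalent form of the unweighted SKAT
variance-component statistic. Because every frequency difference enters
squared, effects in opposite directions accumulate rather than cancel —
the defining contrast with a burden statistic
$\lvert\sum_h (F^+_h - F^-_h)\rvert$, which is included (`stat = "burden"`)
purely for comparison.

Two conventions deserve comment:

* **Norm vs squared norm.** The unsquared norm is the default
  (`stat = "vc"`). The choice is invisible to single-set permutation
  p-values (a monotone transform does not change ranks) but matters for
  SUMSTAT aggregation: with the squared statistic (`stat = "vc2"`) the sum
  of subset statistics equals the single-set statistic for *any* partition,
  so SUMSTAT collapses to the single-set test. That exact identity is kept
  as an engine regression test; the unsquared default makes SUMSTAT a
  genuinely distinct aggregate.
* **Missing genotypes.** Frequencies use per-variant complete-case
  denominators ($2\times$ the number of group members with a non-missing
  call), matching standard allele-frequency practice. A variant with no
  non-missing call in one group is an error rather than a silent `NaN`.

Input counts are assumed minor-allele coded; `orientMinorAllele()` provides
an optional pre-pass that flips variants with overall frequency above 0.5,
for data coming straight from alternate-allele VCF coding.

## The multi-set engine

1. Compute $t_1,\dots,t_m$ on the $m$ subsets.
2. Permute case/control labels $P$ times; recompute to get $s_{ki}$,
   $k = 1..P$. The **same** $P$ permutations are used for every subset,
   preserving the cross-subset dependence structure under the null.
3. Per-subset p-values come from a single shared pool: the observed
   $p_i = (1 + \#\{k: s_{ki} \ge t_i\})/(P+1)$, and each replicate's
   $p_{ki}$ is the rank of $s_{ki}$ within the pooled column
   $\{t_i, s_{1i},\dots,s_{Pi}\}$ with ties counted as "at least as
   extreme". This avoids nested permutation; all p-values live on the grid
   $\{1/(P+1), \dots, 1\}$ and are therefore strictly positive, keeping
   Fisher's logarithms finite.
4. Aggregate and compare to the permutation distribution of the aggregate:
   * **Fisher's** $T = -2\sum_i \ln p_i$, with
     $p = (1 + \#\{k: T_k \ge T\})/(P+1)$. The $\chi^2_{2m}$ upper-tail
     value is reported as a secondary reference (it is exact only for
     independent continuous uniform $p_i$, which permutation grids are
     not), while the primary p-value is the permutation comparison.
   * **SUMSTAT** $T = \sum_i t_i$, same permutation comparison.
   * **Bonferroni** reports $\min_i p_i$ and the cutoff $\alpha/m$, and
     declares significance on the strict inequality
     $\min p < \alpha/m$ — a decision rule, not a p-value, so no
     permutation comparison is involved.

Rejection for the permutation-based methods is $p \le \alpha$; on the grid
$\{1/(P+1),\dots,1\}$ this gives exact size $\alpha$ whenever
$\alpha(P+1)$ is an integer, which holds for the defaults
($\alpha = 0.05$, $P = 199$ or $999$).

### Numerical choices

* **Tie handling under floating point.** Statistics are rounded to 12
  significant digits before any rank comparison. Distinct relabellings can
  be mathematically tied (swapping all case and control labels leaves VC
  unchanged), and identical values computed through different summation
  orders differ by ~$10^{-16}$ relative. Without rounding, such phantom
  differences break the exact partition-invariance of the squared-norm
  SUMSTAT. Genuine differences between count-based statistics at these
  sample sizes are many orders of magnitude larger than the rounding
  threshold.
* **Permutation count.** $P = 999$ is the analysis-mode default
  (p-resolution $10^{-3}$); power studies default to $P = 199$
  (resolution 0.005, sufficient for decisions at $\alpha = 0.05$).
  One caveat: the Bonferroni cutoff $\alpha/m$ must be attainable on the
  grid — with $P = 199$, $m > 10$ makes $\alpha/m < 1/(P+1)$ and the rule
  can never reject. Studies that compare Bonferroni across many $m$ should
  use $P$ large enough that $1/(P+1) \le \alpha/m$ at the largest $m$.
* **Determinism.** A single integer seed fixes the permutation set;
  identical inputs give bit-identical results. In power studies each
  replicate runs from an independently pre-drawn sub-seed, so any single
  replicate can be reproduced in isolation.

## The genotype simulator

Each dataset draws population MAFs $f_h$ i.i.d. from the configured law,
then genotypes as Hardy–Weinberg $\mathrm{Binomial}(2, f)$ draws,
independently across variants. Causal variants are enriched in cases by a
per-allele relative risk $rr$ under retrospective sampling:

$$f^+ = \frac{f \cdot rr}{f \cdot rr + (1-f)},$$

with controls at the population frequency (rare-disease approximation).
This is the simplest generator consistent with a per-variant risk ratio in
a balanced case/control design. Defaults reproduce the reference study
conditions: $l = 1024$ variants, 500 cases and 500 controls, 128 causal
variants (12.5%) at $rr = 1.15$, and `makeScenario()` builds the four
factorial cells crossing equal/unequal subset sizes with equal/unequal
causal concentration. Setting $rr = 1$ gives the null configuration used
for type-I error evaluation. The default MAF law is
$\mathrm{Uniform}(0.001, 0.01)$ — squarely "rare" under the MAF < 0.05
convention — and is configurable per scenario.

What the generator deliberately omits: linkage disequilibrium between
variants, covariates, related individuals, protective effects, and
variant-specific effect sizes (all causal variants share one $rr$).
Passing simulation checks therefore demonstrates correct statistical
behaviour under idealised architecture, not robustness to correlated
genotypes or confounding.

`estimatePower()`/`powerStudy()` report the rejection proportion with its
95% margin of error $1.96\sqrt{\hat p(1-\hat p)/n_{sim}}$ (as a percent;
1.4% at a rate of 0.05 with 1000 replicates, at most 3.1% at 50% power).
Several partitions and all aggregators are evaluated on shared simulated
datasets and shared permutations (common random numbers), which makes
power *differences* between methods considerably more stable than the
individual estimates.

## Reduced-scale study conditions

The test suite exercises the qualitative power behaviour at a scaled-down
design chosen once: $l = 256$ variants, 32 causal, 200 cases / 200
controls, MAF $\sim \mathrm{Uniform}(0.01, 0.05)$, with $rr$ set so that
the contrast under examination sits in the middle of the power range
($rr = 1.45$ for the uninformative-partition comparisons, 1.6 for the
informative ones); type-I error checks run at $l = 256$ with 400
replicates and $P = 199$. Two behaviours of the scaled design are worth
recording:

* Bonferroni's power is not monotone step-by-step in $m$ at this scale:
  when per-subset power is substantial, the min-p rule initially *gains*
  from having several nearly independent tries, and only at fine
  partitions does the $\alpha/m$ penalty dominate. The suite therefore
  asserts the decay across the full range of $m$ (coarsest vs finest
  partition, and against the single-set test), at $P = 999$ so that every
  cutoff is attainable on the p-value grid.
* Fisher's and SUMSTAT pay a real (if modest) price for uninformative
  sub-setting relative to the single-set test; the "tracking" assertion
  uses a one-sided band of 0.15, roughly three standard errors of a power
  difference at 200 replicates.

## Dosage hard-calling

`filterImputedDosages()` implements the post-imputation protocol for real
data: dosages strictly inside $(0.2, 0.8)$ or $(1.2, 1.8)$ become missing
(interval endpoints are kept — the intervals are open), the remainder are
rounded to 0/1/2, and variants are kept only with MAF $< 0.05$ (strict)
and imputation $R^2 > 0.4$ (strict, so $R^2 = 0.4$ exactly is dropped).
MAF is computed from the hardened calls over all samples by default; a
stored (e.g. imputation-panel) MAF can be used instead via
`useStoredMAF = TRUE`, since protocols differ on this point. The filter is
idempotent: applying it to its own output changes nothing.

## Known limitations

* No variant weighting (e.g. by MAF), no covariate adjustment, and no
  asymptotic (mixture-of-chi-square) p-values: inference is purely
  permutation-based, so compute scales linearly in $P$.
* The Bonferroni branch returns a decision plus min-p, not an adjusted
  p-value; combining it with downstream p-value machinery requires the
  per-subset p-values it already exposes.
* Subsets are treated as exchangeable by Fisher's and SUMSTAT; very
  unequal subset sizes effectively down-weight signal in large subsets,
  which is visible in the factorial studies and is a property of the
  method, not an artefact.
* The simulator's independence assumptions (no LD) make permutation
  p-values exact but understate the dependence present in real sequence
  data.
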