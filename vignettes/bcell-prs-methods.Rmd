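---
title: "Methods: pathway-restricted B cell polygenic risk scores for SLE"
author: "BcellPRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-restricted B cell polygenic risk scores for SLE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BcellPRS)
```

# The model

Systemic lupus erythematosus (SLE) is polygenic: no single risk locus
explains disease in an individual, but the weighted burden of many loci
does carry signal. A polygenic risk score (PRS) summarizes that burden as

$$\mathrm{PRS}_j \;=\; \sum_{i} d_{ij}\,\ln \mathrm{OR}_i,$$

where $d_{ij} \in [0,2]$ is the risk-allele dosage of variant $i$ in
individual $j$ and $\mathrm{OR}_i$ the published per-allele odds ratio for
SLE. This package restricts the sum to a curated pathway: the packaged
weight table holds 20 SLE risk variants mapped to B cell function genes
(the *B cell PRS*), 12 of which, in genes restricted to B cell activation,
form the nested *B cell activation PRS*. Pathway membership is input data
— the package never re-derives it from pathway databases.

Weights are stored as `log(or_sle)` at full double precision, computed from
the table's odds ratio rather than from pre-rounded weights, so sums are
bit-reproducible. When a listed allele is protective (OR < 1) the variant is
re-oriented (`orientWeights()`): alleles swapped, OR inverted, frequency
complemented. Scores therefore always accumulate towards risk, and
orientation is idempotent.

Scores are analysed both continuously and binarized at the within-cohort
third quartile: *high* means strictly above the 75th percentile (type-7,
linear interpolation — the estimator is stated because the source analysis
does not define one, and the tie policy makes tests exact), *low* means
quartiles 1–3. The quartile is computed within whatever cohort is passed to
`classifyQuartiles()`; the caller decides whether that is patients only or
patients plus controls.

## Missing dosages

The study cohort this mirrors was imputed genome-wide, so missingness is
silent there; here a missing dosage is imputed by its Hardy–Weinberg
expectation $2\,\mathrm{raf}_i$ and counted per sample in `n_missing_used`,
which keeps the score unbiased in expectation and the imputation auditable.
Allele-label mismatches are resolved by strand flip only for non-ambiguous
pairs; A/T and C/G mismatches abort, because a silent strand error inverts
the contribution of a locus.

# Genotype quality control

`runQC()` applies the chain in the order used for the source cohort, each
stage computed on the survivors of the previous one, and records the stage
of every exclusion:

1. **Sample call rate** < 95% (strict; a sample exactly at 95% is kept).
2. **PCA outliers**: variants standardized with mean imputation, samples
   more than 5 SD from the mean on any of the top 10 components flagged.
   Flagging is relative to the cohort itself; pre-computed reference
   coordinates (e.g. a projection onto an external reference panel) can be
   supplied instead, which keeps the operation self-contained while
   preserving the contract.
3. **Relatedness**: PLINK-style method-of-moments IBD from IBS sharing and
   allele frequencies (re-implemented from the published estimator, with
   component probabilities truncated to $[0,1]$ and renormalized);
   pairs with $\hat\pi > 0.1875$ lose the lower-call-rate member
   (tie: the later sample ID), deterministically.
4. **Heterozygosity outliers**: autosomal heterozygous fraction more than
   5 SD from the cohort mean.
5. **Sex check**: X-chromosome inbreeding coefficient
   $F = (O_{hom}-E_{hom})/(n-E_{hom})$ with the usual $n_i/(n_i-1)$
   small-sample correction in $E_{hom}$; annotated males with $F < 0.8$ and
   annotated females with $F > 0.2$ are excluded, unknown sex is never
   excluded by this rule.
6. **Variant filters**: call rate < 98%, MAF < 0.01, Hardy–Weinberg exact
   test $p < 10^{-4}$ on non-missing autosomal counts.

The HWE test is the exact conditional test (recurrence over heterozygote
counts given allele totals) rather than chi-square — robust at MAF near
0.01 and checkable against an independent closed-form enumeration, which
the test suite does exhaustively for all tables of up to 200 individuals.
Ties in configuration probability are included in the p-value with a
$1+10^{-9}$ relative guard so that equal-probability configurations are not
split by floating-point noise.

LD pruning (`ldPrune()`) uses composite genotype correlation (dosage
Pearson $r^2$, phase-free): while any kept pair exceeds $r^2 > 0.2$,
the lower-OR member is dropped (ties: lower RAF, then lexicographically
larger rsID), so the highest-OR variant represents each locus and the
result is deterministic.

Two practical notes on the estimators' resolution, visible in the test
fixtures: the moments IBD estimator needs on the order of a thousand
markers before its null noise (with truncation-induced upward skew) stays
safely below the 0.1875 threshold, and the X-linked $F$ needs several
hundred X markers before female estimates stay under the 0.2 bound. A
genuinely aberrant sample (e.g. a gross heterozygosity excess) also
distorts IBD with *every* partner — a known interaction of the stage order,
which places relatedness before heterozygosity filtering.

# Association analysis

All association output is an effect estimate with Wald 95% CI and p-value
on complete cases, mirroring the symmetric-on-log-scale intervals of the
reported tables; no multiplicity adjustment is applied (nominal p-values,
with the number of tests attached to the battery result).

- `compareMeansTTest()`: classical pooled-variance Student's t for patient
  vs control mean scores.
- `logisticAssoc()`: ML logistic regression of a binary outcome on the
  high-PRS indicator, adjusted for years of disease duration. Perfect
  separation raises an error advising an exact/penalized model instead of
  silently reporting an absurd estimate.
- `stratifiedAssoc()`: the same fit inside each HLA stratum, no pooling and
  no interaction term; strata that cannot be fitted are reported
  not-estimable without aborting the rest. Stratified analyses keep the
  duration adjustment.
- `coxAssoc()`: proportional-hazards fit of time to nephritis onset with
  Breslow tie handling (stated for determinism; Efron differs negligibly at
  these scales), adjusted for age at onset.
- HLA strata come from tag SNPs rs1269852 (HLA-DRB1\*03:01) and rs3135388
  (HLA-DRB1\*15:01) under dominant coding: carrier of neither / exactly
  one / both.

# The synthetic cohort generator

The study's patient-level data are not public, so the generator emulates
the statistical structure the analysis assumes; its defaults *are* the
study conditions: 1248 female patients and 400 controls; Hardy–Weinberg
genotypes at the published patient-cohort risk-allele frequencies, controls
at the frequencies implied by inverting the per-allele odds ratios
(`deriveControlFreq()`); outcome prevalences from the published patient
characteristics (e.g. renal disorder 29.7%, anti-dsDNA 62.6%); HLA strata
drawn at the published 354 : 656 : 143 proportions with tag-SNP dosages
consistent with each stratum; and effect sizes from the published
associations (`defaultEffectSpec()`).

Binary outcomes are drawn from a logistic model on the high-PRS indicator
(quartile-level effects are modelled directly on the indicator rather than
re-derived from per-allele effects, since the two are not mutually
constrained by the published results; the allelic case/control frequency
difference is modelled separately and independently), with the intercept
calibrated by bisection to the configured marginal prevalence to
$|\Delta| < 10^{-6}$. Renal disorder is generated last so its model can
carry both the activation-PRS indicator effect and the
nephritis-vs-dsDNA log-odds, reproducing the qualitative dsDNA → nephritis
coupling. Nephritis onset times are exponential with the published
log-hazard on dsDNA status plus a small age term, censored by an
independent exponential capped at 40 years.

Distributions not published beyond medians/ranges are chosen once and
documented as arbitrary: disease duration log-normal with median 18 years
(`sdlog` 0.7), age at onset log-normal with median 35 years (`sdlog` 0.45),
covariate effects 0.02/year (duration, log-odds) and 0.01/year (age,
log-hazard), baseline nephritis hazard 0.02/year, censoring rate 0.04/year.
Loci are independent (no LD) by default; `addCorrelatedVariants()` exists
solely to exercise the pruning code.

What the generator does **not** emulate: LD structure, population
stratification, genotyping error, informative censoring, or the cohort
structure that makes the observed patient mean B cell PRS (2.92) exceed the
Hardy–Weinberg expectation $\sum_i 2\,\mathrm{raf}_i \ln \mathrm{OR}_i
\approx 1.84$ computed from the same table — that discrepancy cannot be
resolved from the published values and is deliberately not modelled, so
passing tests validate the pipeline's arithmetic and inference, not those
empirical means. The score distribution is approximately Gaussian in the
histogram sense but measurably right-skewed (the low-frequency, high-weight
*TNFAIP3* locus dominates the upper tail); tests check moments and QQ
linearity rather than an omnibus normality test, which any finite lattice
sum fails at large n.

# Parameter recovery and its limits

`recoverEffect()` regenerates data under one packaged generating model and
re-estimates the effect per replicate; the acceptance suite checks that the
mean recovered log-effect sits within 3 standard errors of the generating
value over 200 replicates. At cohort size (n = 1248) the ML estimates are
effectively unbiased and these checks pass comfortably. In the 143-patient
double-positive HLA stratum, however, the ML log odds ratio carries a
first-order small-sample bias of about +0.09 for effects of the published
size (OR ≈ 4–4.5 with a 25% exposed fraction), so the geometric mean of
recovered odds ratios converges to ≈ 4.9 against a generating 4.47. The
recovery suite measures this honestly rather than hiding it; the same bias
inflates any single published ML estimate from a stratum of that size. A
penalized (Firth) fit would remove it but would no longer be the estimator
the analysis specifies.

Statistical calibration is verified separately: 95% CI coverage between 93%
and 97% and type-I error near 5% for both the logistic and Cox stages over
500 null simulations.

# Problem sizes and determinism

Simulations in the test and acceptance suites are sized to be decisive yet
quick on a single CPU: 200 replicate cohorts per recovered effect (500 for
the small-stratum designs in the acceptance script), 100,000 patients for
the prevalence calibration check, 500 null simulations for coverage, and an
exhaustive HWE sweep to n = 200. Every stochastic step takes an explicit
seed; cohorts are bit-reproducible given the seed, and pipeline artifacts
are byte-identical across re-runs (timestamps excepted, in the manifest
only).

# Known limitations

- The generator couples outcomes only through the modelled effects; real
  ACR criteria are mutually correlated beyond what the PRS induces.
- Controls carry genotypes but no clinical columns, matching the
  blood-donor design; analyses that would need control phenotypes are
  therefore not representable.
- PCA outlier flagging is cohort-relative by default; with very small
  cohorts the components are noisy and the stage is skipped below
  `n_components + 1` samples.
- The IBD estimator assumes approximately independent markers; applying it
  to the 20 packaged loci alone is refused by the overlap floor.
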