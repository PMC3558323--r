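---
title: "Scoring genomic instability from array-CGH profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genomic instability from array-CGH profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g2i)
```

## Overview

`g2i` implements a two-parameter genomic instability index for tumor
copy-number profiles measured on BAC arrays. A profile is a vector of
normalized log2 tumor/normal ratios, one per clone, ordered along the
genome. The pipeline is:

1. **Segmentation and smoothing** of the log2 ratios into a
   piecewise-constant fit per chromosome.
2. **GNL calling**: each clone becomes gain (+1), normal (0) or loss (−1)
   by comparing its smoothed value with the sample's autosomal residual
   standard deviation.
3. **Local-score smoothing** of the GNL vector to absorb isolated
   single-clone artifacts.
4. **Index computation**: A (mean per-arm altered fraction) and N (number
   of altered regions), then a grade in {1, 2, 3} from four thresholds.

Downstream modules cluster GNL profiles into genomic archetypes, call
amplicons, and connect grades to outcome (odds ratios, chi-square tests,
logistic regression, Kaplan–Meier/log-rank). A synthetic cohort generator
provides ground truth for end-to-end validation.

## Segmentation

The segmenter minimizes, over all tilings of a chromosome into segments of
at least `min_seg_len` clones,

$$\sum_{\text{segments}} \sum_{i \in \text{seg}} (y_i - \bar y_{\text{seg}})^2
  \;+\; \lambda \cdot \#\text{segments},$$

solved exactly by an $O(n^2)$ dynamic program over breakpoint positions
(optimal partitioning with cumulative sums). This is a deliberate
substitute for the GLAD-style smoothing used on the original platform: the
downstream contract is only a deterministic piecewise-constant fit, and an
exact penalized least-squares fit is transparent, testable against
exhaustive enumeration on short chromosomes, and fast at array scale
(about 0.1 s per 5,878-clone profile).

Numerical choices:

- **Penalty** `penalty`, log2² units. Default
  $\lambda = 2\hat\sigma^2\log n$ per chromosome (BIC-like), with
  $\hat\sigma$ a per-sample robust noise scale — the median absolute
  deviation of successive within-chromosome differences divided by
  $\sqrt2$. A supplied penalty of 0 is lifted to $10^{-9}$ so that ties in
  fit are always resolved toward fewer segments; among equal-cost optima
  the dynamic program deterministically picks the earliest breakpoints.
- **`min_seg_len`** defaults to 2 clones: single-clone segments are
  artifacts at BAC resolution; a chromosome shorter than `min_seg_len`
  becomes one segment.
- **Missing clones** are skipped (segmentation runs on the observed clones
  of each chromosome; missing entries stay `NA` in the smoothed output).

## GNL calling

A clone is a gain when its smoothed value strictly exceeds
`sd_multiplier × residual SD` of its sample, a loss below the negative
threshold, normal otherwise. The residual SD is the sample standard
deviation (n − 1 denominator) of `normalized − smoothed` over autosomal
clones only, so sex-chromosome dosage does not inflate the noise estimate.
The multiplier defaults to 1.0 ("more than the standard deviation") and is
exposed as a knob. Values exactly at the threshold stay normal.

Each sample gets its own threshold; whether the original analysis used one
global or per-sample cut-off is not recoverable, and per-sample thresholds
are the natural choice when hybridization quality varies. A residual SD of
exactly 0 (a degenerate noise estimate, e.g. noise-free synthetic data)
produces a warning; calls are still made, so any non-zero smoothed value
becomes an event.

## The index

- **A** — for every autosomal chromosome arm with at least one usable
  clone, the proportion of non-missing clones with status ≠ 0; A is the
  unweighted mean over arms. Arms without usable clones are dropped from
  the average (with a warning) rather than imputed. Sex chromosomes are
  kept in the profiles but excluded from A, N and the residual SD.
- **N** — the number of maximal runs of non-normal status, counted within
  chromosomes (a run never spans two chromosomes; a gain run adjacent to a
  loss run counts as two regions) and summed over autosomes. N counts
  altered runs, not all status transitions: with regions defined by
  "difference with respect to the neighbours", an altered segment is one
  region regardless of which side of it changes.
- **Local score smoothing** (applied before N): any maximal run shorter
  than `min_run` whose two flanking runs agree on a status is reassigned
  that status, iterated to a fixed point. `min_run` defaults to 2 — only
  isolated single clones are absorbed — which is the weakest
  artifact-removal rule; the exact rule used upstream of the published
  counts is not recoverable, so the substitute is documented rather than
  claimed identical. The operation is idempotent and can only decrease N.
- **Missing-data runs**: clones with missing status are excluded; a run is
  bridged across a gap of up to four consecutive missing clones and broken
  at gaps of five or more, so localized array dropouts neither create nor
  destroy breakpoints.

### Classification

With thresholds $(a_1, n_1, a_2, n_2) = (0.48, 42, 0.35, 65)$:
grade 1 if $A < a_1$ and $N \le n_1$; grade 3 if $A > a_2$ and
$N \ge n_2$; grade 2 otherwise. The source material states the boundary
inequalities in two conflicting ways (strict in the index pseudo-code,
inclusive on N in the results prose and figure legend); the package
adopts strict-on-A / inclusive-on-N as default and exposes
`boundary = "strict"` for the all-strict variant. With the default
thresholds the grade-1 and grade-3 predicates cannot both hold (N cannot
be both ≤ 42 and ≥ 65), so the three rules partition the (A, N) plane;
the grade-1 rule is evaluated first for custom thresholds that overlap.

### Threshold search

`optimize_thresholds()` is a documented substitute for the original
under-specified calibration: an exhaustive grid search over
$(a_1, n_1, a_2, n_2)$ scoring each candidate by the deviance of the
logistic model of outcome on the resulting grade factor. Because that
model is saturated in grade, the deviance has a closed form from the
per-grade event rates (the unit tests verify it against `glm`). Ties are
broken toward fewer grade-2 samples, then lexicographically; overlapping
regions ($a_1 \ge a_2$) are allowed, as in the published values.

## Clustering, frequency screens, amplicons

The distance between GNL profiles defaults to 1 − Pearson correlation of
the status vectors (missing clones pairwise-excluded) with Ward
(`ward.D2`) linkage; both are substitutes, since the original
distance/linkage are not in the main text, and Manhattan distance and
average linkage are provided as options. A constant (all-normal) profile
has no defined correlation: identical constant pairs get distance 0 and
any other pair involving a constant profile distance 1, with a warning —
so flat profiles co-cluster instead of scattering. k defaults to 6 (the
archetype count chosen qualitatively in this literature) with no automatic
selection.

`differential_regions()` screens clone-by-clone with two-sided Fisher
exact tests (gains and losses separately) and reports maximal runs passing
both the raw p-value filter (default ≤ 10⁻⁴) and the focal-group
frequency filter (default ≥ 50%). No multiplicity correction is applied:
the published rule is a filter on raw p-values, and the reported values
are raw.

Amplicons are maximal runs of at least `min_clones = 2` contiguous clones
with inferred copy number above `cn_threshold = 3`, where
CN = `ploidy × 2^smoothed` under a diploid, fully cellular tumor
(ploidy and cellularity are not estimated; `ploidy` is a parameter). At
defaults the rule is equivalent to smoothed > log2(3/2) ≈ 0.585. Calling
is on smoothed segment means, not raw probes, because the rule describes
region-level copy number.

## Statistics layer

- `odds_ratio_wald()`: cross-product OR, Wald 95% CI
  ($\exp(\log\text{OR} \pm 1.96\,\text{SE})$, SE = √(Σ 1/cell)), two-sided
  Wald p. Zero cells get the Haldane–Anscombe +0.5 correction, flagged in
  the output; a zero margin is an error.
- `pearson_chi_square()`: Pearson statistic without continuity correction
  (the published table p-values recompute exactly under the uncorrected
  test), df = (r−1)(c−1).
- `logistic_regression()`: maximum-likelihood logistic fit via `glm`
  (IRLS, convergence tolerance 10⁻¹⁰). Perfect separation is detected
  (diverging slope plus the fitted-probability warning) and raised as an
  error naming the covariate, rather than returning a diverged fit. In
  grade-based models grade 2 is the natural reference category.
- `km_logrank()`: product-limit curves via `survival::survfit`, log-rank
  test via `survdiff`; for two groups the hazard ratio is
  (O₁/E₁)/(O₂/E₂) from the log-rank observed/expected counts — not a Cox
  model, matching how the HR is attributed in this setting.

## Expression signature

`welch_t_signature()` computes per-probe Welch t-tests (unequal variances,
Satterthwaite df) between the grade-3 group and the rest, two-sided, and
selects probes with raw p < 5×10⁻³ — no multiplicity correction, matching
the derivation rule; a BH-adjusted mode exists but is off by default.
Probes with zero variance in both groups are skipped with a warning.
Clustering on the signature reuses the correlation/Ward engine, and
`centroid_classify()` assigns new samples to the nearest class centroid by
Pearson correlation on shared probes (at least 50% of the signature
required; ties within 10⁻¹² are returned as "unclassified").

## The synthetic cohort generator

The generator emulates the study conditions, not any particular dataset:

- **Array geometry**: 5,878 clones allocated to chromosome arms
  proportionally to arm length (approximate GRCh37 lengths and
  centromeres), evenly spaced with uniform jitter, giving a median
  inter-clone spacing close to 0.5 Mb. Acrocentric p arms (13, 14, 15,
  21, 22) carry no clones, so A averages over the 39 clone-bearing
  autosomal arms.
- **Six archetypes** mirroring the recurrent aCGH patterns of breast
  tumors: flat (`flat_a`, no events by definition), 1q+/16q−
  (`t1q16q_b`), 1q+ with whole-chromosome-7 gain (`c1q7_c`), the 8p−/8q+
  16p+/16q− arm swap (`chr8_16_d`), a many-arm complex pattern
  (`complex_e`), and a firestorm pattern (`firestorm_f`) with few arm
  events but a storm of focal rearrangements and frequent amplicons.
- **Event load**: background focal-event counts are Poisson — mean 45
  (lengths 3–12 clones) for the arm-driven archetypes, 50 for the complex
  pattern, 85 with longer events (15–45 clones) for the firestorm —
  chosen once so that cohort N values span the published dynamic range
  (tens of regions for arm-driven tumors, near a hundred for firestorms,
  cohort mean around 65). Segment means are −0.5 (one-copy loss), +0.4
  (one-copy gain) and +1.0 (amplicon, CN 4) in log2 units, so one-copy
  events exceed the default probe noise (Gaussian, sd 0.1) after
  smoothing; all are configurable.
- **Placement** is greedy and non-overlapping: events keep at least two
  normal clones between each other and never strand a single normal clone
  at a chromosome end (a single stranded clone would be unresolvable for the
  2-clone-minimum segmenter, making zero-noise truth recovery ambiguous).
- **Outcomes**: relapse is Bernoulli conditional on the planted grade
  only, with default probabilities 1/19, 23/88 and 21/28 for grades
  1/2/3 — the published relapse fractions. Relapsers get event times
  uniform on (6, 120) months; non-relapsers are censored beyond 131
  months, the study's minimum follow-up. The other clinical covariates
  (node status, age, size, SBR grade, hormone receptors, NPI, Mib1, TP53,
  intrinsic class) are drawn with grade-conditional frequencies matching
  the published 135-tumor cross-tabulations.

What the generator does **not** emulate: tumor cellularity and normal-cell
contamination (segment means are full-amplitude), spatial array artifacts
and wavy baselines, correlated probe noise, the dependence of relapse on
anything but grade, and real linkage between co-occurring events beyond
the archetype recipes. Pipeline tests on these cohorts therefore validate
the algorithmic chain — segmentation, calling, counting, classification,
clustering recovery, statistical machinery — under the stated noise model;
they do not certify performance on real hybridizations, where
normalization quality and cellularity dominate.

## Problem sizes and test design

The test suite validates each stage against an independent oracle:
segmentation against exhaustive enumeration of breakpoint sets on
chromosomes of up to 20 clones; Fisher p-values against direct
hypergeometric summation; the chi-square p against a 100,000-table
Monte-Carlo permutation oracle (on a 3×3 table of 135 samples with all
expected counts ≥ 11, the regime where the asymptotic reference is
accurate at Monte-Carlo resolution); Welch statistics against
`stats::t.test` per probe; logistic odds ratios against the closed-form
2×2 OR; the log-rank statistic against a hand-tabulated risk-set
computation. Cohort-level properties use fixed seeds: 20-sample
single-archetype cohorts for grade recovery, 120 samples (6 × 20) for
clustering recovery, 100 replicates of 135-tumor cohorts for
confidence-interval coverage of the grade-3 relapse odds ratio.

## Known limitations

- The segmentation, local-score rule, clustering distance/linkage and
  threshold calibration are documented substitutes for under-specified
  originals; exact reproduction of the original cohort's cluster
  memberships or region counts is out of scope.
- Coordinates are treated as opaque (the source platform's genome build is
  unstated); the built-in arm table is approximate and replaceable.
- Copy-number inference assumes diploidy and full tumor cellularity.
- The hazard ratio comes from log-rank O/E ratios; no Cox or competing
  risks modelling.
- The expression module starts from a normalized log2 matrix; no
  CEL-level preprocessing or probe-to-gene annotation.
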