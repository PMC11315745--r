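---
title: "Methods: D-dimer cut-off strategies, diagnostic performance, and cost minimization"
author: "ddcea authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: D-dimer cut-off strategies, diagnostic performance, and cost minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcea)
```

## The problem

Cancer patients have chronically elevated D-dimer, so the conventional
0.5 mg/L rule-out threshold for suspected venous thromboembolism (VTE)
loses specificity in this population: many patients without VTE exceed it
and are sent to confirmatory imaging (CT pulmonary angiography for
suspected pulmonary embolism, compression ultrasound for suspected deep
vein thrombosis) that a better cut-off would have avoided. Because
D-dimer also rises with age, several adjusted thresholds have been
proposed. This package compares six strategies on a common cohort and
prices the imaging examinations each one avoids:

| id | strategy | threshold (mg/L) |
|----|----------|------------------|
| m1 | conventional rule-out | 0.5 |
| m2 | age-adjusted | 0.5 up to age 50, then age × 0.01 |
| m3 | inverse age-adjusted | 0.5 + (66 − age) × 0.01 below 66, else 0.5 |
| m4 | increased fixed | 1.0 |
| m5 | specificity-targeted | smallest observed value with ≥ 95% control values below it |
| m6 | ROC-optimal | observed value maximizing Youden's J |

A patient is **negative** (VTE excluded, imaging avoided) when their
D-dimer is strictly below their threshold; a value exactly at the
threshold is positive. This tie rule is fixed and documented rather than
configurable: a rule-out decision should err toward imaging at the
boundary, and the convention makes the data-derived cut-off finders
well-defined on tied data.

Two boundary decisions in the age-adjusted rules were genuinely open and
are resolved as follows. "Over 50" is read strictly, so age 50 still uses
0.5 mg/L. The inverse age-adjusted formula would fall below 0.5 mg/L
from age 67 on; it is clamped at 0.5 mg/L, because a rule-out threshold
below the assay's own 0.5 mg/L convention would label patients negative
whom every other strategy, and the assay's reference range, would send to
imaging.

## The synthetic cohort generator

The study data are access-controlled, so the package ships a generator
(`generate_cohort()`) calibrated to the published age-stratified summary
table: 526 patients, 152 with adjudicated VTE (83 PE / 69 DVT) and 374
controls, in eight age groups per arm with a median and IQR (mg/L) each.
The generator is first-class, tested code; its defaults *are* the study
conditions and are not tuned.

**Marginal law.** Within each age group, D-dimer is log-normal — the
standard stand-in for a positively skewed biomarker reported as
median/IQR. `fit_lognormal_median_iqr()` pins `mu = log(median)` and
`sigma = (log(q75) − log(q25)) / (2 qnorm(0.75))`, the symmetric-quartile
approximation; the implied quartiles reproduce the printed IQR exactly
when the printed quartiles are log-symmetric about the median, and to a
close approximation otherwise. The two groups printed with n = 1 carry no
IQR and inherit the overall-arm sigma.

**Hard constraints.** The published table contains counts that the
original analysis treats as exact, so the generator enforces them exactly
for every seed rather than in expectation:

* every VTE patient's value exceeds 0.5 mg/L **and** the thresholds of
  the zero-false-negative strategies (m1–m3 by default) at that patient's
  age — those strategies' printed 100% sensitivity / 0 false negatives is
  reproducible only by construction;
* exactly `n_below_10` VTE patients per group (6 overall) lie in the band
  between that personal floor and 1.0 mg/L, and all other VTE values are
  at or above 1.0 mg/L — making the increased fixed cut-off's 6 false
  negatives exact, not approximate;
* exactly `n_below_05` controls per group (219 overall) lie below
  0.5 mg/L.

Each stratum is sampled from the fitted log-normal restricted to its
interval by inverse-CDF sampling (exact for thin intervals; a rejection
loop could stall). Infeasible constraint sets — a quota exceeding its
group, or an enforced threshold at or above 1.0 mg/L squeezing the
sub-1.0 band shut — raise a classed error naming the group.

**Everything else.** Ages are uniform integers within group bounds, with
the open-ended extremes bounded at [18, 24] and [86, 100]. The PE/DVT
split is apportioned across age groups by largest remainder (the
per-group split is unpublished) and assigned randomly within groups. PE
implies the CTPA pathway and DVT the CUS pathway; controls are CTPA with
probability `control_ctpa_fraction` (default 0.5 — the study never
reports the split, and the pathway-level cost results depend on it, which
is why it is a configuration knob). Pretest probability is carried as a
field but never computed: cases draw moderate/high (0.7/0.3), controls
low/moderate (0.6/0.4). Values are recorded to 4 decimal places
(assay-scale precision), nudged off stratum boundaries so the exact
counts survive rounding; this also makes CSV round trips lossless and
reruns byte-identical. The generator restores the caller's RNG state.

**What the calibration does and does not claim.** The printed group
medians are rounded to one decimal and are not always mutually consistent
with the printed sub-threshold quotas (e.g. the 46–55 control group
prints median 0.5 mg/L yet 37/65 = 57% below 0.5). The stratified design
takes the quotas as exact, so its *implied* group medians — computable in
closed form from the fitted law and the strata — deviate from the printed
medians by up to ~9% in the VTE arm and more where the printed numbers
conflict. The calibration tests therefore check sample medians against
the implied medians and, separately, that the VTE implied medians stay
within 10% of the printed ones. No age–D-dimer copula is imposed: the
positive rank correlation between age and D-dimer (the study reports
r = 0.166) emerges from the group-level differences alone, and the test
suite asserts only its sign, across seeds.

The generator emulates summary-table structure, not patient-level
reality: within-group distribution shape, the control pathway split, and
the pretest field are modelling choices. Passing tests show the pipeline
reproduces the published arithmetic and count structure under these
conditions; they do not validate the strategies on real patients, and the
data-derived cut-offs (m5, m6) resolve to synthetic-cohort values, not
the published 4.9 / 9.9 mg/L, which depend on the unavailable
patient-level data.

## Diagnostic performance

`confusion_table()` counts the 2×2 cells per rule and scope. The study
never states which controls enter its PE and DVT subgroup analyses; here
scoped analyses pair PE cases with CTPA-pathway controls and DVT cases
with CUS-pathway controls, which is why printed subgroup specificities
are not expected to reconstruct exactly.

Sensitivity, specificity, predictive values, and likelihood ratios follow
their standard definitions; ratios with zero denominators are reported as
`NA`, mirroring the dashes in published tables. All internal math is
unrounded; `format_metrics()` applies half-up display rounding (integer
percentages, one-decimal ratios) at the formatting layer only.
`metrics_from_summary()` reconstructs counts from printed
sensitivity/specificity (half-up on `sens × n_pos` etc.) for predictive
values, but computes likelihood ratios directly from the quoted
proportions — reconstructed counts re-round the proportions and would not
reproduce the published ratios.

The AUC is the Mann–Whitney statistic (ties half credit), and its
variance uses DeLong's placement components: with cases `x_i` and
controls `y_j`, `V10_i = mean_j psi(x_i, y_j)` and
`V01_j = mean_i psi(x_i, y_j)` give
`var(AUC) = var(V10)/m + var(V01)/n`; the Wald interval is clipped to
[0, 1]. The implementation is cross-checked in the tests against pROC (to
machine precision), a stratified bootstrap, and a coverage simulation on
binormal data. Spearman correlation is the Pearson correlation of
mid-ranks with a two-sided t-approximation p-value, matching
`cor.test(..., exact = FALSE)`.

## Cost minimization

All strategies test everyone, so D-dimer costs cancel and only imaging
enters savings. A patient's examination is saved exactly when the
reference rule (m1 by default) calls them positive and the evaluated rule
calls them negative; counts split by pathway. Savings are
`counts × price` under each schedule — the shipped files encode the
German medical fee schedule (CUS €18.89, D-dimer €24.13, CTPA €209.83)
and published US averages (CUS $184, D-dimer $14, CTPA $648) exactly as
printed.

Rounding is a pipeline, not a property: components and totals are kept
unrounded internally, display values are rounded half-up to whole
currency units, and annualization scales the **unrounded** total by
`annual_total / cohort_n` (5475/526 by default) before display rounding.
Rounding before annualizing would not reproduce the published annual
figures. The overall 5475/526 factor is used rather than separate
1825/PE and 3650/DVT factors because only the overall factor reproduces
the published annual savings; the per-pathway volumes are retained in
`annual_volume()` for scenario analyses. One published component resists
half-up rounding: 5 CUS × €18.89 = €94.45 prints as €95 in the source;
the package reports €94 and the discrepancy is noted here rather than
special-cased.

Percent cost reduction needs a baseline the source never defines; the
default (`reference_pathway_cost()`) is, within a pathway subgroup, one
D-dimer test per patient plus imaging for every reference-positive
patient. It is explicit and configurable, not a reconstruction of the
published 8.1%/3.4%/4.6%/1% figures, whose denominators are unprinted.
The ROC-optimal rule is excluded from cost runs by default — its
false-negative count makes it unsafe as a rule-out strategy — and can be
re-included explicitly.

## Orchestration and reproducibility

`run_vte_analysis()` drives cohort → rule resolution → evaluation → cost
→ report from a validated `run_config()`; misconfiguration fails before
any computation. Outputs (cohort CSV for synthetic runs, metrics and
savings as CSV and JSON, a human-readable summary, provenance with seed,
package version, resolved thresholds, and a config hash) contain no
timestamps, so an identical config and seed reproduces every file byte
for byte; the provenance hash covers the analytic configuration only, not
the output location. A thin command-line wrapper
(`system.file("scripts", "ddcea.R", package = "ddcea")`) exposes
simulate/evaluate/cost/run subcommands with distinct exit codes for
configuration errors (2), infeasible constraints (3), and degenerate data
(4).

## Numerical choices and problem sizes

* Half-up rounding everywhere a display value is produced (base `round()`
  is half-even and disagrees with published figures on .5 boundaries).
* Data-derived cut-off candidates are the observed values plus infinity,
  the empirical-ROC convention; Youden ties break toward the lower
  threshold.
* Truncated-interval feasibility floor: 1e−6 probability mass.
* Degenerate inputs (no cases, no controls, constant vectors, empty
  scopes) raise classed errors rather than NaN.

The test suite works at deliberately modest sizes chosen to make the
checks exhaustive or near-exhaustive while staying quick: brute-force AUC
and Youden oracles on cohorts of up to 60 patients, a 2000-replicate
bootstrap at 20 cases/20 controls, 500 binormal replicates at 40/40 for
interval coverage, 200 seeds for generator calibration and 120 for the
median-recovery and rank-correlation checks.

## Known limitations

* Published AUCs (0.942/0.950/0.932), subgroup specificities, the
  percent-reduction figures, and the specificity-targeted /
  ROC-optimal false-negative counts depend on unavailable patient-level
  data or unprinted denominators and are not reproduction targets; the
  corresponding machinery is validated by property tests and oracles
  instead.
* The source reports overall specificity 65% for the conventional
  cut-off, while its own summary table implies 219/374 = 58.6% of
  controls below 0.5 mg/L; these are irreconcilable from the printed
  data. The synthetic cohort reproduces the count (219), not the
  percentage.
* The source's inconsistent per-subgroup false-negative sums for the
  ROC-optimal rule (96 overall vs 35 + 52) are treated as descriptive,
  not as contracts.
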