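---
title: "Methods: traffic-light zoning, AIDA classes, and the prediction harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: traffic-light zoning, AIDA classes, and the prediction harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aidalabor)
```

## The problem and the model

During a protracted second stage of labor (beyond three hours in a
nulliparous patient under neuraxial analgesia), the obstetric question is
whether labor will end in an intrapartum cesarean delivery (ICD) or a
vaginal delivery (operative or spontaneous). The AIDA (Artificial
Intelligence Dystocia Algorithm) approach answers it from four geometric
parameters measured by transabdominal intrapartum ultrasound:

* **AD** — asynclitism degree, mm: lateral tilt of the fetal head,
  measured as the distance between the cranial midline and the leading
  parietal bone;
* **AoP** — angle of progression, degrees: descent of the head relative
  to the pubic symphysis;
* **HSD** — head-symphysis distance, mm;
* **MLA** — midline angle, degrees: rotation of the cranial midline
  relative to the pelvic axis.

Each parameter is coded into a traffic-light **zone** — green (low risk),
yellow (cut-off band), red (high risk) — and the **AIDA class** is the
count of parameters outside their green zone, from 0 (all green) to 4
(none green). The class is the interpretable risk summary; alongside it,
three machine-learning classifiers (random forest, RBF support vector
machine, single-hidden-layer perceptron) predict the binary ICD/non-ICD
outcome directly from the four raw measurements.

The package reproduces that pipeline end to end: zone coding, class
computation, the pairwise decision-tree procedure that generated the
published cut-offs, the seeded 70–30 prediction harness, the Pearson
correlation report, and the class-stratified evaluation that rebuilds the
published per-class performance table from the published per-patient
prediction tables, which ship as machine-readable fixtures.

## Zone thresholds and boundary conventions

The published thresholds are: AD green below 65.5 mm, yellow in
[65.5, 70.5) mm, red at or above 70.5 mm; AoP green in [101.5, 144.5)
degrees, red on either side; HSD red at or above 19.5 mm. Intervals are
half-open `[lo, hi)` with the topmost interval closed, so a red threshold
printed as "&ge; t" maps t itself to red. Only AD has a published yellow
band; the other parameters default to two-zone schemes, and every
threshold is an argument of `default_zone_scheme()`.

The MLA red threshold is the one genuinely open choice: the study inherits
it from its antecedent and does not print it (its cut-off table's MLA
column is blank, and one published class-3 row shows an MLA yellow label
whose band is likewise unprinted). The default here is **45 degrees**, the
conventional midline-angle cutoff for clinically significant malrotation
in the intrapartum-ultrasound literature; it is deliberately configurable
because any analysis of real data should set it from its own evidence.
Values outside the observed study ranges (e.g. AD above 95 mm) are still
zoned but trigger a warning, since the thresholds carry no evidence out
there.

Classes 1 and 2 are computed by the same counting rule even though the
published analysis covers only classes 0, 3 and 4 — the class is defined
for all five values.

## The synthetic cohort: what it emulates, and what it does not

The study's raw measurements are held by its authors and not deposited, so
the package includes a generator whose defaults are the published study
conditions: per-parameter minimum/maximum/mean/SD, the published pairwise
Pearson correlations (AD–AoP 0.36, AD–HSD 0.18, AD–MLA 0.14,
Apgar1–Apgar5 0.8, AD–Apgar −0.2/−0.19; unreported pairs 0), an anterior
asynclitism fraction of 50/135, and an outcome mix targeting the study's
56 ICD / 22 ICD-after-failure / 31 operative vaginal / 26 spontaneous
counts.

Design of the generator:

* **Gaussian copula with truncated-normal marginals.** Only means, SDs,
  ranges and pairwise Pearson coefficients are published; this is the
  minimal joint model consistent with all of them. Any richer dependence
  (tail dependence, nonlinearity) is unconstrained by the publication and
  deliberately not modelled.
* **Inverse-CDF truncation, not rejection.** Each latent normal score is
  mapped through the truncated-normal quantile function. This keeps the
  copula's rank structure exact (rejection resampling of out-of-bounds
  records would distort it) and makes cost deterministic. Configured
  correlations are therefore recovered on the *latent* scale
  (`latent_scores()`); the observed-scale Pearson coefficient is mildly
  attenuated by truncation, most visibly for HSD, whose lower bound sits
  1.2 SD above the publication's minimum.
* **Moment-matched marginals.** Truncating a normal with the published
  mean/SD to the published range shifts its moments (for AD the mean drops
  by ~1.3 mm), so the generator solves for the latent mean/SD that give
  the truncated distribution exactly the published mean and SD
  (`calibrate_tnorm()`, closed-form moments + Nelder-Mead).
* **Outcome model.** ICD is drawn from a logistic model in the AIDA class
  with anchors P(ICD | class 0) = 0.02 and P(ICD | class 4) = 0.98,
  mimicking the published per-patient tables where class 0 contains no
  cesarean rows and class 4 only cesarean rows; both anchors are
  arguments. With the default zone scheme this yields an expected ICD
  fraction of ≈ 0.57, close to the study's 78/135 ≈ 0.578, so no further
  calibration is applied. Positives split ICD : ICD-after-failure at
  56:22, negatives OVD : spontaneous at 31:26.
* **Seeding.** One root seed is split into named substreams (geometry,
  Apgar, outcome, asynclitism type, demographics), so adding a sampler
  never perturbs earlier streams and every cohort is bit-reproducible.

What passing tests on this cohort do **not** show: the generator has no
measurement error model, no within-hospital clustering, no association
between asynclitism type and geometry (none is published), and its
class-outcome link is exactly the logistic model the tests then probe. It
validates the *machinery* — zoning, derivation, harness, evaluation — not
the clinical claims, which rest on the study's own data.

```{r gradient}
cohort <- generate_cohort(n = 135, seed = 1)
prof <- zone_profile(cohort)
tapply(binary_outcome(cohort$delivery_outcome) == "ICD",
       prof$aida_class, mean)
```

## Cut-off derivation

The published cut-offs were produced by a decision tree on parameter pairs
(AoP–AD, HSD–AD, MLA–AD) against the binary outcome. The package's
`derive_pair_cutoffs()` implements that procedure as a deterministic CART:
Gini impurity, candidate thresholds at midpoints of consecutive distinct
sorted values (hence the `x.5` character of every published threshold),
maximum depth 2 (the published AoP rule — ICD when AD &ge; 67 with AoP
&ge; 144.5 or &lt; 101.5 — requires depth 2), minimum leaf size 1, no
pruning, ties broken toward the smaller threshold and the first feature.
Splits must strictly decrease impurity, so a no-signal cohort yields an
empty cut-off set; a single-class cohort is an error.

The published thresholds themselves (70.5 / 65.5 / 19.5 / 101.5 / 144.5 /
67) **cannot be re-derived** without the raw cohort; they ship as
constants in the default zone scheme and in the cut-off fixture. The
derivation is instead validated by construction: on a synthetic cohort
with a hard rule (ICD iff AD &ge; 70 mm) the recovered threshold must land
in the inter-point gap around 70, and depth-1 splits are checked against a
brute-force enumeration oracle on small instances and against an
independent CART implementation (rpart) on a clean cohort. How the study
reconciled its three pairwise AD thresholds (67, 70.5, 65.5) into the
single 65.5/70.5 yellow band is asserted in the publication but not
specified algorithmically, and is not modelled here.

## The prediction harness

`make_split_plan()` draws one simple random, unstratified 70–30 partition
per seed; the default seeds (1, 0, 250, 500, 750) and fraction give the
study's five 95/40 splits at n = 135. The train size is
`floor(0.7 n + 0.5)`, i.e. 94.5 rounds up to the published 95. The
original tooling's seed-to-partition map is proprietary, so the printed
seed values are honored as labels of independent partitions; exact
reproduction of per-patient predictions is not expected — the exact
reproduction target is the evaluation of the published prediction tables.

Learner settings are unpublished; the defaults are the smallest standard
configurations, chosen for determinism and exposed as arguments: random
forest with 100 trees; RBF SVM with cost 1 and gamma 1/4 on z-scored
features; a single-hidden-layer perceptron with 8 units, weight decay
1e-4 and a fixed 500-iteration cap (no early stopping); optional
classification-tree and logistic-regression learners. Features enter tree
learners raw and are z-scored (train-fitted only) for the scale-sensitive
SVM and MLP. Feature importance uses impurity for trees, absolute
standardized coefficients for logistic regression, and seeded permutation
importance on held-out data for SVM/MLP.

Per-patient prediction records aggregate one row per patient and distinct
prediction pattern with a repetition count, so the expanded total per
algorithm is seeds × test size (200 at n = 135) — the accounting identity
behind the published "86 unique patients with 149 predictions" across the
three analysed classes.

## Evaluation conventions

Confusion matrices take cesarean delivery as the positive class and, by
default, expand records by repetition count, since the published totals
(68 / 50 / 31 per class) are expanded counts. The six metrics follow the
publication's undefined-as-NA convention: a metric is NA exactly when its
denominator is zero, and F1 is NA when PPV or recall is NA or when both
are zero. The published table fixes one subtle corner: an all-negative
class with one false positive has PPV printed as 0.00 but F1 printed NA
(because recall is undefined) — the rule above reproduces all 14 NA cells.
Metric comparisons against the published table round the exact count
ratios to four decimals before comparing, which avoids float-formatting
false mismatches at the table's mixed 3–4-decimal precision.

```{r table}
tab <- reproduce_performance_table()
tab[, c("aida_class", "algorithm", "tp", "fp", "fn", "tn",
        "accuracy", "ppv", "recall", "f1")]
```

## Correlation report

`pearson_test()` uses the exact t transform on n − 2 degrees of freedom
(the published p of 8.42 × 10⁻³² is far beyond permutation resolution).
Strength bands are half-open at 0.20/0.40/0.60/0.80 — consistent with the
published table labelling 0.18 "very weak" and −0.2 "weak" — and
significance stars use strict thresholds (p = 0.05 exactly earns no
star). The publication's own text once calls the −0.19 coefficient "weak"
while its table says "very weak"; the band definition here sides with the
table.

## Problem sizes and numerical choices

The test suite and the analysis scripts use n = 10,000 for Monte-Carlo
recovery (standard error ≈ sd/100 on means, ≈ 0.01 on correlations, well
inside the ±3 SE and ±0.05 acceptance bands) and n = 135 — the study
size — for everything structural. Truncated-normal moment matching stops
at a relative moment error of 10⁻³ SD or better; correlation matrices
that fail positive semi-definiteness (possible under user-supplied
correlations) are repaired by eigenvalue clipping with a warning; leaf
ties in the CART go to the positive class; degenerate inputs (constant
series, single-class cohorts, empty selections) error or warn explicitly
rather than returning silent values.

## Known limitations

* The published cut-offs, feature-importance rankings and the
  111-distinct/89-repeat split of the study's 200 predictions depend on
  the unreleased raw cohort; they are packaged as fixtures and checked
  structurally, never re-derived.
* The MLA threshold default is a literature convention, not a published
  study value.
* The synthetic cohort recovers published *pairwise* structure only; any
  conclusions about joint tail behaviour or real-data performance are out
  of reach by design.
* Learner hyperparameters are this package's defaults, not the study's
  (which are unpublished); harness outputs on synthetic data are
  structural demonstrations, not claims about the study's algorithms.
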