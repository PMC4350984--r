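---
title: "Determining the therapeutic role of radiotherapy from treatment records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the therapeutic role of radiotherapy from treatment records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtrole)
```

## The problem

Radiotherapy is delivered either with curative aim or for palliation of
incurable disease, and the two settings are prescribed very differently:
curative courses use many small daily fractions (typically 15--35 fractions
of about 200 cGy), palliative courses use few large ones (1--10 fractions of
300--800 cGy). Population-level research on radiotherapy utilisation and
outcomes needs to know which role each treatment played, but administrative
record-and-verify data often carry an "intent" label that is missing,
inconsistently coded, or simply wrong. `rtrole` derives the therapeutic role
from the treatment parameters that are always captured at the machine --
dose per fraction, irradiated body region, primary disease site, and the
time elapsed since the patient's first treatment for the same cancer -- and
provides the machinery to quantify how well both the derived classification
and the recorded intent label reflect the truth.

## The classifier

The core model is a binary chi-square recursive-partitioning tree (a
CHAID-style inducer restricted to two-way splits). At each node every
candidate binary split of every classification variable is scored with the
Pearson chi-square statistic on the 2x2 table of split side by intent
class,

$$X^2 = \frac{n\,(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},$$

on one degree of freedom with no continuity correction (splitting happens
at large n). For a continuous variable the candidates are the midpoints
between consecutive distinct observed values; a record with value greater
than or equal to the threshold descends to the right child. For a
categorical variable the observed levels are sorted by their palliative
proportion and the k−1 contiguous cuts of that ordering are the candidates
-- for a two-class outcome the chi-square-optimal binary partition is
always contiguous in this ordering, so the reduction is exact, and an
exhaustive enumeration oracle guards it in the test suite. Each variable's
candidate p-values are Bonferroni-adjusted by the number of candidates
evaluated for that variable, `p_adj = min(1, m * p)`. The most significant
split (smallest adjusted p; ties broken by larger statistic, then variable
order, then smaller threshold) forms the branching, and growth stops when
no candidate reaches the retention threshold with both children large
enough. Leaves are labelled by their majority intent class.

Tunable induction parameters (`induction_params()`):

* `alpha` (default 0.2) -- retention threshold on the *adjusted* p-value.
  Applying the threshold after adjustment is the stricter of the two
  possible readings and is the package's choice.
* `min_node` (default 400 records) -- minimum size of **each** child of a
  split; the constraint is interpreted as binding on both children, which
  is the conservative reading of "a further split would lead to a group
  with less than 400 records".
* `continuous_threshold_cap` (default 64) -- at most this many thresholds
  per continuous variable per node, taken evenly spaced in rank order of
  the midpoints. This bounds the work per node without materially moving
  large-sample splits: with the default, each gap between consecutive
  candidates carries about 1.5% of the node's records.
* Leaf-label ties (exactly 50/50) go to curative, the majority class
  overall.

## Missing predictors: the model cascade

Administrative data are incomplete: in the reference profile roughly 1% of
records lack a usable dose per fraction, 9% a body-region group and 3% a
disease-site group, while the treatment date is always present. Instead of
imputing, `build_cascade()` grows one tree per variable subset -- by
default the seven subsets that always include time from first treatment --
and ranks them by their misclassification rate on a held-out validation
partition (ties prefer the larger subset, then the smaller model id).
`classify_with_cascade()` sends every record to the highest-ranked model
whose variables it has; a record that no model can handle is reported as
unclassifiable, never defaulted. For complete records the cascade is
exactly the rank-1 tree. Whether ranking should use the validation or the
test partition is not fixed by the problem; the package ranks on the
validation partition, which is also where each model's accuracy is
reported.

## Rules

`extract_rules()` converts a tree into one conjunctive rule per leaf by
collecting the conditions along the root-to-leaf path. Rules are kept
mutually exclusive and unsimplified so that rule application provably
equals tree descent record for record (a property the suite checks on
hundreds of random trees). `render_rules()` writes them in a small
versioned plain-text grammar with units (cGy, days) that `parse_rules()`
reads back losslessly; numbers are printed in the shortest plain-decimal
form that round-trips exactly.

## Validation and the stratified audit

`split_dataset()` partitions records 40/30/30 into training, validation
and test sets by seeded multinomial assignment. `confusion_matrix()`
reports accuracy with a 95% Wilson score interval together with the two
off-diagonal rates (curative-called-palliative and vice versa), which sum
with accuracy to exactly 1.

Because the intent flag itself is unreliable, internal validation against
it bounds agreement, not correctness. The audit machinery estimates true
error rates from a manual review of a patient-stratified random sample:
`stratified_audit_sample()` draws a seeded simple random sample of
patients within strata (typically centre x period x whether the
classification agrees with the intent flag) and attaches every treatment
the sampled patients received; `stratified_estimates()` projects the
audited confusion counts to the population with expansion weights
$w_h = N_h/n_h$, so that e.g.

$$\widehat{\text{sens}} = \frac{\sum_h w_h\,TP_h}{\sum_h w_h\,(TP_h+FN_h)}.$$

Confidence intervals for these ratios use a normal approximation with a
linearised (Taylor) variance; simple proportions use Wilson intervals. The
audit unit is the patient but metrics are computed over treatment records
of sampled patients; clustering of records within patients is *not*
propagated into the interval widths, a known limitation that makes the
intervals somewhat anti-conservative. `population_quality_report()`
produces the three-row summary (% correct / % incorrect / % missing) for
both the classifier and the intent flag; the intent flag's missing share
is observed directly from the full data set rather than estimated, and an
audit design that samples only disagreement records must assume unaudited
agreement records are correct -- the report exposes this as an explicit
option (`unaudited = "assume_correct"`) and the suite demonstrates the
resulting upward bias in % correct relative to a full random audit.

## The synthetic generator

No administrative radiotherapy extract is publicly deposited, so
`generate_records()` simulates the record structure end to end: patients
receive one course (plus, with probability 0.15, a later re-treatment that
is palliative with probability 0.9), courses are consecutive weekday
fractions with a constant prescribed dose per fraction, and sites/regions
are drawn from a coarse editable joint frequency table shipped as CSV
data. Defaults are calibrated to the reference profile: 14% of records
palliative, curative doses centred at 200 cGy and palliative at 300 cGy
(medians the suite verifies), per-variable missingness of 1/9/3/0%, and
intent noise of 4% flips with 18.8% missing (3.4% is the corresponding
modern-period missing share).

Two design choices deserve a note. First, the course role is a
cluster-level draw: the first-course palliative probability is solved
analytically from the regimen means, the re-treatment rate and the target
record share, and the observed share therefore fluctuates at the course
level, not the record level -- tests use a course-level standard error
accordingly. Second, intent noise is a per-record three-way draw (missing
with the configured missing rate, flipped with the flip rate, otherwise
faithful) rather than two sequential independent corruptions; this makes
the configured rates directly equal the population shares of missing and
incorrect intent, which is how the three-row quality report tabulates
them. Dose and course length are drawn independently within a role, which
real prescriptions are not (an 800 cGy course is nearly always a single
fraction); none of the shipped analyses are sensitive to that joint.

`generate_from_tree()` is the recovery harness: it draws records uniformly
within the feature regions of a fully labelled tree and assigns the leaf
label as the true role with a configurable purity, so the Bayes classifier
of the generated population is the tree itself. The suite grows trees on
50,000 such records (purity 0.95) across 20 seeds and requires the
fraction-size root with a threshold within one candidate gap of the
generative 277 cGy boundary and at least 95% held-out agreement -- sizes
chosen so the whole experiment runs in well under a minute per seed while
the boundary gaps of the threshold cap stay below the purity noise floor.

What passing these tests shows -- and what it does not: the generator
reproduces the marginal regimen structure, missingness and label noise of
real administrative data, but not centre-to-centre practice variation,
protocol drift over time, hypo-fractionated curative regimens for specific
sites, or miscoded body regions. Performance figures obtained on synthetic
data therefore validate the *machinery* (induction, cascade, rules,
estimators), not the clinical accuracy of any particular fitted tree.

## The published reference tree

`published_tree()` encodes the partial structure of the reference
classifier derived from the Ontario data, to the extent its paths are
stated in text: the 277 cGy root; the high-dose body-region branch whose
bone/brain/chest/abdomen/neck/pelvis side is palliative; the
prostate/head-neck/skin curative site branch; and a time split at 75 days
(about two and a half months) on the low-dose side. End points whose
labels are not recoverable carry the label `"unspecified"` and supports
are `NA`; the fixture is intentionally partial and is meant for worked
examples and contract tests, not as a substitute for fitting to local
data.

## Degenerate inputs and numerical conventions

* A 2x2 table with a zero marginal is degenerate: statistic 0, p 1, so a
  pure node never splits.
* A constant variable contributes no candidates; a node smaller than
  `2 * min_node` cannot split.
* Threshold comparisons are `>=` to the right, matching the reference
  tree's "greater or equal to 277 cGy".
* A record whose value at some split is missing -- or, for categorical
  splits, outside both stored category sets (a level never seen in
  training) -- is not routed; the blocking variable is reported and the
  cascade is the intended fallback.
* ICD-9 codes are 3-digit integers; longer codes truncate. Codes outside
  the shipped grouping (e.g. 145, 166--169, 176--178) map to
  `"ungrouped"` rather than erroring.
* Dates are ISO-8601 at day granularity; no time zones.

## Problem sizes used by the shipped checks

The test suite and the acceptance script exercise the pipeline at sizes a
laptop handles comfortably: synthetic populations of 1,300 patients
(roughly 25,000 daily records), 200 random data sets for the split-search
oracle, 50 trees by 10,000 records for rule/tree equivalence, and 20
seeded recovery runs of 50,000 records each. These sizes were chosen as
the smallest at which the statistical tolerances (3 binomial or
Monte-Carlo standard errors) are tight enough to be informative.
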