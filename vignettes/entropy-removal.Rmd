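---
title: "Entropy removal: measuring how much diagnostic uncertainty a feature takes away"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy removal: measuring how much diagnostic uncertainty a feature takes away}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagentropy)
```

## The model

A dichotomous clinical feature — a symptom, a demographic trait, a lab
result, an imaging finding — splits a patient population into a
test-positive group and a test-negative group. `diagentropy` treats this
split exactly as a decision tree treats a node split and asks how much
of the *diagnostic uncertainty* about disease status the split removes.

Before the feature is observed, uncertainty about disease status is the
Shannon entropy of the prevalence,

$$H_{\mathrm{parent}} = -\pi \log_2 \pi - (1-\pi)\log_2(1-\pi),$$

with $\pi$ the prevalence. A binary outcome bounds this at 1 bit. After
the split, the residual uncertainty is the size-weighted average of the
child entropies, each again taken over disease status *within* the
node:

$$H_{\mathrm{children}} = \frac{n_+}{N} H(\mathrm{TP}, \mathrm{FP}) +
  \frac{n_-}{N} H(\mathrm{FN}, \mathrm{TN}),$$

where $n_+ = TP + FP$ and $n_- = FN + TN$. **Entropy removal** is the
difference

$$ER = H_{\mathrm{parent}} - H_{\mathrm{children}},$$

which is identical to the mutual information between the test and
disease indicators — the package's test suite checks this equivalence
against an independent mutual-information implementation on tens of
thousands of random tables, so $ER \ge 0$ always. The quantity used
throughout the downstream analysis is the *fraction*
`er_fraction` $= ER / H_{\mathrm{parent}}$, the share of baseline
uncertainty removed. Two reasons for preferring the fraction: it is
invariant to the logarithm base (a property also under test), and it is
comparable across disease contexts with very different prevalences,
whereas raw bits are capped by $H_{\mathrm{parent}}$ and so conflate
feature quality with prevalence. Absolute bits are reported alongside
(`er_bits`; entropies are computed in base 2 by decision-tree
convention).

A perfect feature (sensitivity = specificity = 1) produces two pure
children and removes 100% of entropy. A feature independent of disease
(sensitivity $= 1 -$ specificity) reproduces the parent distribution in
both children and removes nothing. Between those poles the fraction
responds to sensitivity, specificity *and* prevalence jointly — which
is precisely why it is not redundant with accuracy metrics: a test with
excellent sensitivity and specificity applied at very low prevalence
can achieve a high Youden's J while removing little uncertainty,
because the parent node held little entropy to begin with and the
positive child stays impure.

### Assumptions

* The feature is dichotomous and summarized by a single 2×2 table;
  continuous markers must be dichotomized upstream.
* One feature at a time: no joint or sequential information of feature
  combinations is modelled.
* The table (or the prevalence/sensitivity/specificity/N quartet it is
  derived from) is taken at face value; sampling error in the published
  estimates is not propagated.

## From performance parameters to counts

Rows that report prevalence, sensitivity, specificity and total N
instead of raw counts are converted with

$$TP = \pi\,se\,N,\quad FP = (1-\pi)(1-sp)N,\quad
  FN = \pi(1-se)N,\quad TN = (1-\pi)\,sp\,N.$$

The FN formula is forced by conservation of the disease margin:
$TP + FN$ must equal $\pi N$. Cells are deliberately **not rounded** to
integers — entropies and metrics are functions of proportions, and
rounding would inject up-to-half-a-patient distortions at small N for
no statistical benefit. Fractional cells are therefore first-class
throughout. When a row carries both counts and parameters they are
cross-checked (1e-6 relative); counts win on conflict because they are
the primary observable, and the row is flagged with a warning.

## Accuracy metrics and the odds-ratio edge case

Alongside entropy removal the package computes sensitivity,
specificity, PPV, NPV, Youden's $J = se + sp - 1$ and the diagnostic
odds ratio $DOR = (TP \cdot TN)/(FP \cdot FN)$. A zero cell makes the
DOR 0, infinite or undefined; since perfect tests genuinely occur in
this kind of data, the package applies the Haldane–Anscombe correction
(+0.5 to all four cells) whenever any cell is zero, flags the row
(`dor_corrected`), and keeps the uncorrected sentinel
(`dor_uncorrected`). The corrected value is what enters the logged-DOR
correlation, so perfect tests are retained rather than dropped and the
correlation sample stays the full table; dropping them instead is a
one-line filter on the flag if a user prefers. `log_dor` uses the
natural log — Pearson correlations are invariant to the base, so the
choice is cosmetic.

## The quadrant framework

Each feature is placed in one of four quadrants by comparing $J$
(accuracy axis) and the ER fraction (information axis) to cutoffs,
both inclusive on the high side:

| quadrant | condition |
|---|---|
| High Accuracy / High Information | $J \ge 0.60$ and $ER \ge 0.40$ |
| High Accuracy / Low Information  | $J \ge 0.60$ and $ER < 0.40$ |
| Low Accuracy / High Information  | $J < 0.60$ and $ER \ge 0.40$ |
| Low Accuracy / Low Information   | $J < 0.60$ and $ER < 0.40$ |

The defaults 0.60 and 0.40 are the conventional cutoffs for this
framework; both are exposed as parameters (`j_cut`, `er_cut`) and
echoed in every summary and manifest so any re-analysis is
self-describing. No sensitivity analysis is implied by the defaults —
the parameterization exists exactly so users can run one.

Feature categories are a closed vocabulary of four names
(Demographics, Imaging, Lab/Diagnostic Tests, Signs/Symptoms/History),
matched case-insensitively on ingestion; anything unrecognized is
preserved but tallied under *Other* with a warning, which keeps
third-party tables loadable without silently mangling their labels.

## Correlation analysis

`correlation_report()` correlates the ER fraction with each of the six
accuracy metrics using the two-tailed Pearson coefficient, p-values
from the t distribution on $n-2$ degrees of freedom. Rows with an
undefined metric (e.g. PPV when $TP+FP=0$) are excluded *per metric*,
not listwise — each correlation keeps the largest defensible sample,
and the exclusions are itemized in the report's `excluded` attribute.
No multiple-comparison adjustment is applied; the analysis is
descriptive. A degenerate metric column (constant, or fewer than three
usable rows) produces an error entry for that metric only.

## The synthetic cohort generator

`generate_cohort()` produces feature tables with the statistical
structure of a literature-derived table of 405 clinical features from
23 systematic reviews, so that every pipeline stage is testable without
any external download. Per row it draws, in a fixed order (category,
prevalence, sensitivity, specificity, N):

* **category** — multinomial with weights 3/405, 160/405, 65/405,
  177/405 over Demographics, Imaging, Lab/Diagnostic Tests,
  Signs/Symptoms/History, the category mix of the emulated table;
* **prevalence** — Uniform(0.01, 0.60): bounded away from 0 and 1 so
  the parent entropy is always positive (the ER fraction is undefined
  at prevalence 0 or 1), and truncated at 0.60 because diagnostic
  accuracy studies rarely enrol case-majority samples;
* **sensitivity, specificity** — independent Beta(5, 2) draws (mean
  ≈ 0.71, right-skewed): clinically typical operating points with a
  realistic tail of weak features, which yields the qualitative
  pattern of mostly-modest ER with a high tail;
* **N** — $\mathrm{round}(10^{U(2,\,3.5)})$, i.e. review sample sizes
  from 100 to ~3000, log-uniform.

Two kinds of **planted controls** (defaults: 5 of each per cohort) have
analytically known answers: perfect features (sens = spec = 1, true ER
fraction exactly 1) and independent features (sens $= 1 -$ spec
exactly, true ER exactly 0). They are drawn from a separate RNG
sub-stream keyed off the main seed, so adding or removing planted rows
never perturbs the regular rows. Every generated row carries its
analytic ground truth (computed at generation time via the
mutual-information route, not the parent/child decomposition the
pipeline uses), and `ground_truth_check()` verifies recovery to 1e-9 —
this parameter-recovery loop is the package's primary end-to-end
correctness argument.

**What the generator does not emulate** — and hence what passing
recovery tests do *not* show about real data: sensitivity and
specificity are drawn independently and from the same distribution,
whereas real features exhibit a correlated, asymmetric joint structure
(many features combine extreme specificity with mediocre sensitivity);
rows are independent, whereas real tables nest features within shared
reviews and diseases; and the generator does not target the empirical
inter-metric correlation pattern of any particular dataset. Analyses
whose answer depends on that joint structure — notably the *ordering*
of ER's correlations with the six metrics — can only be checked against
the real source table, which users can supply via
`options(diagentropy.source_data = "...")` and run through
`replicate_study()` or the `replicate` CLI command.

## Numerical choices

* $0 \log 0 = 0$ everywhere; an empty child node contributes zero
  entropy with zero weight (required for perfect tests).
* ER is provably non-negative; floating-point cancellation can produce
  values like $-10^{-16}$, which are clamped to 0. Anything below
  $-10^{-12}$ is treated as a genuine numerical failure and raised.
* Probability vectors must sum to 1 within 1e-9; proportions are
  validated to [0, 1] with the offending field named in the error.
* Degenerate inputs raise classed conditions
  (`zero_parent_entropy_error`, `degenerate_margin_error`,
  `degenerate_variance_error`, `schema_error`) rather than returning
  NaN, so callers can isolate per-row failures — the batch pipeline
  catches them, routes the rows to a rejects report, and continues.
* Results CSVs serialize floats to 6 significant digits; round-trip
  tests hold at 1e-6.

## Problem sizes used by the test suite

The suite generates all fixtures in code: cohorts of 405 rows for
recovery and summary checks (matching the size of the emulated table),
10,000 random tables for the mutual-information equivalence bound at
1e-10, and grids of a few hundred points for the quadrant partition and
independence properties. The whole suite runs in well under a minute on
one core.

## Known limitations

* Single-feature analysis only; no conditional entropy chains over
  feature sequences.
* No confidence intervals on metrics or on ER; no likelihood-ratio
  reporting.
* The Pearson analysis assumes the usual linearity/normality caveats;
  no rank-based alternative is provided.
* Replication of the published 405-feature analysis requires the
  user-supplied source table; the package bundles only its reference
  values (`published_reference()`) for comparison.
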