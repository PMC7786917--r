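---
title: "The FI-30 deficit-accumulation frailty index: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FI-30 deficit-accumulation frailty index: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fi30)
```

## The deficit-accumulation model

A deficit-accumulation frailty index treats ageing-related decline as the
proportion of health deficits an individual has accumulated out of a fixed
list of candidate deficits. `fi30` implements a 30-item instrument for
community-dwelling older adults: self-reported conditions and activities of
daily living, two performance tests (tandem balance, chair stand), and four
measurement-derived items (BMI, blood pressure, random blood sugar, and the
GDS-15 depression screen). Each item is coded to a deficit weight in
[0, 1] — 0 for absence, 1 for full presence, with intermediate ordinal
grades (0.25, 0.33, 0.5, 0.66, 0.75) for items that admit partial severity.
The index is

$$FI = \frac{\sum \text{deficits}}{30 - \sum \text{missing}}$$

so that missing items shrink the denominator rather than being imputed as
healthy. The index is kept at full floating precision internally; rounding
happens only in report writers, because severity classification must precede
rounding.

Severity is classified into four right-closed bands: **fit** (FI ≤ 0.12),
**mild** (0.12 < FI ≤ 0.24), **moderate** (0.24 < FI ≤ 0.36) and **severe**
(FI > 0.36); a boundary value belongs to the less severe band, and FI = 0 is
fit by construction. The binary collapse at FI = 0.24 (fit vs frail) is the
outcome of the logistic risk-factor model.

```{r}
compute_fi(c(rep(1, 7), rep(0, 21), NA, NA))
categorize_fi(c(0.12, 0.13, 0.28, 0.5))
```

## Parameters that matter, and their defaults

* **Completeness threshold** (`min_items`, default 24 of 30). The FI formula
  never bounds its denominator; with very few answered items the index
  becomes an unstable ratio. We require 80% completeness — a common
  convention for deficit indices — and raise an error below it. The study
  cohort this package emulates had no missing values, so the default never
  binds there; it exists for real survey data.
* **Severity cut points** (0.12 / 0.24 / 0.36, right-closed). These are the
  standard electronic-frailty-index bands; they are constants of the
  instrument, not tuning knobs.
* **Measurement grade cut points.** The instrument defines the RBS bands
  itself (< 7.9 / 7.9–14.9 / ≥ 15.0 mmol/L); the printed bands leave
  [14.9, 15.0) unassigned, which we resolve as a half-open middle band so
  every non-negative value grades. The BMI, BP and GDS items name only grade
  labels, so the package supplies documented, configurable defaults: WHO
  adult BMI bands with underweight pooled into the 0.5 grade (underweight is
  itself a deficit in elderly cohorts); WHO/ISH hypertension grades 1–3 with
  the worse of the systolic and diastolic grade; and the standard GDS-15
  screening bands 0–4 / 5–9 / 10–15. All three accept `cuts` overrides, and
  the pipeline manifest echoes every resolved cut point.
* **Label matching** in `code_item()` is case-insensitive after trimming, a
  robustness choice for survey data entry; anything not in the scheme is a
  hard error naming the item and label, never a silent coercion.

## The association layer

The analysis layer reproduces the statistical toolkit of a cross-sectional
frailty survey:

* `crosstab()` builds the covariate-level × severity count table and its
  binary collapse; `chi_square()` runs the Pearson test on the full
  four-category table (no continuity correction), flagging expected counts
  below 5.
* Two odds conventions are provided deliberately. `subgroup_frailty_odds()`
  is the *within-level* frail/fit odds on the binary collapse — the
  convention that reproduces the "unadjusted OR" column of the published
  risk-factor table this package emulates. `odds_ratio()` is the textbook
  reference-contrast 2×2 cross-product with a Woolf interval (optionally
  Haldane–Anscombe corrected). The report writer wires the subgroup
  convention into the reproduction table and keeps the textbook estimator
  alongside.
* `fit_logistic()` is maximum-likelihood logistic regression (IRLS, up to
  100 iterations, deviance tolerance 1e-10 — in practice indistinguishable
  from a coefficient-change criterion; univariable estimates agree with
  closed-form 2×2 odds ratios to well below 1e-6 in the tests). Wald
  standard errors come from the inverse observed information; intervals use
  z = 1.959964 and reference levels carry no estimate. Complete separation
  and rank deficiency raise classed errors naming the offending term —
  separation is reported, not repaired (no Firth correction), matching the
  reporting practice of the emulated study. No multiple-testing correction
  or survey weighting is applied, for the same reason.
* `prevalence_ci()` defaults to the Wilson score interval (the published
  figure does not state a method; Wilson behaves well at the small fit
  counts involved), with Wald available for comparison. `fi_t_test()` is the
  pooled two-sample t, accepting raw vectors or printed summary triplets —
  the published male/female comparison (n = 229, mean 0.271, SD 0.118 vs
  n = 171, 0.303, 0.114) gives p = 0.0068, consistent with the printed
  0.006 at rounding. `cronbach_alpha()` is the plain variance-ratio form.

```{r}
ct <- as_crosstab(fi30_table_counts()$gender, "gender")
chi_square(ct)
subgroup_frailty_odds(ct, "Female")
odds_ratio(ct, "Female", "Male")
```

## What the synthetic cohorts emulate — and what they do not

Individual-level data for the emulated study are not public, so the
generators define the study conditions the package is validated under.

**Table-faithful mode** regenerates a 400-subject cohort whose every
covariate × severity cross-tab equals the shipped count matrices *exactly*,
for every seed: subjects get categories per the column totals
(34/120/145/101), and within each category block each covariate's levels
are dealt by a seeded permutation. Only the margins of the joint covariate
distribution are published, so covariates are **conditionally independent
given category** — an explicit minimal assumption, stated here because it
is exactly what passing cross-tab tests do *not* establish about real data:
any statistic driven by covariate–covariate dependence within a severity
band (e.g. a multivariable adjusted OR) is not pinned down by this mode.
FI values are drawn uniformly within the assigned band, clipped to the
observed range [0.05, 0.71]; a `grid` sampler restricted to FI values
attainable as legal weight sums (multiples of 1/60) is offered for work
that cares about the index's arithmetic. Under the uniform sampler the
expected cohort mean FI is ≈ 0.30, inside the 0.24–0.32 bracket the tests
assert and consistent with the 0.28 the emulated cohort reports. The
optional **deep mode** synthesizes 30 item-level responses per subject by
seeded rejection sampling (severity-graded draws around the target load,
200 attempts, deterministic fallback), so the full coding path is exercised
end to end.

**Parametric mode** draws covariates independently from declared level
probabilities, the frail outcome from a Bernoulli with
logit⁻¹(intercept + Σ indicator effects), and FI from class-conditional
uniforms ((0.24, 0.71] frail, [0.05, 0.24] fit). Because the truth is
known, this mode supports the recovery evidence for the quantities no
printed table can verify: over 500 replicates at n = 2000 the absolute
bias of recovered coefficients stays below 0.1 and 95% Wald coverage sits
in [0.92, 0.98]. Ages, when wanted for calibration displays, come from a
truncated normal (mean 63.61, SD 8.73, range 55–100) respecting each
subject's age band.

Both generators take an explicit seed, restore the caller's RNG state, and
are bit-reproducible end to end (cohort → report bundle), which the test
suite checks file by file.

## Numerical and design choices

* Boundary ties at 0.12/0.24/0.36 go to the less severe class — read
  directly off the band inequalities.
* The chi-square runs on the four-category table, as the published
  association table does, not on the binary collapse.
* The within-level odds convention was adopted after verifying numerically
  that it (and not the reference-contrast OR) reproduces the published
  unadjusted column from the cross-tab counts for the age, gender,
  education, occupation and income rows. The marital-status, family-type,
  religion and smoking rows of that table match neither convention and are
  excluded from reproduction tests.
* The published adjusted ORs depend on the unpublished joint covariate
  distribution and one is internally inconsistent (OR 1.487 with CI
  0.84–2.64 yet p = 0.0174); they are not reproduction targets — the
  adjusted model is instead validated by parameter recovery.
* Report floats print at 3 decimals by default; JSON summaries keep full
  precision. The run manifest excludes machine-specific paths so a
  configuration reruns byte-identically anywhere.

## Problem sizes

The shipped validation uses the cohort sizes the analyses are designed
for: 400-subject table-faithful cohorts, parametric cohorts of
2,000–10,000, 500 recovery replicates in the test suite and 300 in the
acceptance summary script. These are the package's chosen study
conditions; all run in seconds to a few minutes on one CPU.

## Known limitations

* No alternative frailty instruments (Fried phenotype, FRAIL scale), no
  longitudinal trajectories, no imputation beyond the denominator
  adjustment.
* No survey weighting or cluster-robust variance: the emulated analysis
  reports none, and the generators have no cluster structure.
* The table-faithful generator cannot — by construction — inform about
  within-category covariate dependence; conclusions about adjusted
  estimates on real data need real joint data.
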