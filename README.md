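# fi30 — deficit-accumulation frailty index (FI-30) scoring and cohort analysis

`fi30` is an R package for epidemiologists and biostatisticians analysing
frailty in cross-sectional surveys of community-dwelling older adults. It
implements a 30-item deficit-accumulation Frailty Index — the instrument,
its ordinal deficit coding, and the full analysis pipeline built on it —
plus seeded synthetic-cohort generators for validation when individual-level
data are unavailable.

## The model

Each of 30 health deficits (self-reported conditions, activities of daily
living, performance tests, and measurement-derived items for BMI, blood
pressure, random blood sugar and GDS-15 depression) is coded to a weight in
[0, 1]: 0 absent, 1 present, with ordinal grades 0.25/0.33/0.5/0.66/0.75 for
partial severity. The index for a subject is

    FI = Σ deficits / (30 − Σ missing)

Missing items shrink the denominator (no imputation); subjects with fewer
than 24 of 30 answered items are refused a score. Severity is classified
into right-closed bands — fit (FI ≤ 0.12), mild (0.12, 0.24], moderate
(0.24, 0.36], severe (> 0.36) — and dichotomized at FI = 0.24 into fit
vs frail, the outcome of the logistic risk-factor model.

The association layer provides severity cross-tabs with Pearson chi-square,
within-level frailty odds (the convention behind published "unadjusted OR"
columns) alongside the conventional 2×2 odds ratio with Woolf interval,
binary logistic regression with Wald 95% intervals (univariable and
multivariable), Wilson/Wald prevalence intervals, the pooled Student t-test
(raw vectors or printed summary triplets), and Cronbach's alpha.

## Worked example

```r
library(fi30)

cohort <- generate_table_faithful(seed = 42)   # 400 subjects, cross-tabs fixed
calibration_report(cohort)
#> Cohort calibration (n = 400)
#>   FI: mean 0.307 (SD 0.163), range 0.052-0.709
#>   Severity proportions: FIT 0.085, MILD 0.300, MODERATE 0.362, SEVERE 0.253
#>   Frail prevalence: 0.615

ct <- crosstab(cohort, "gender")
chi_square(ct)
#> Pearson chi-square = 10.963, df = 3, p = 0.01193
subgroup_frailty_odds(ct, "Female")
#> subgroup_odds = 2.226 (95% CI 1.61-3.08)

fit_logistic(cohort, c("age_group", "gender"), mode = "univariable")
#> univariable logistic model (n = 400, converged in 4 iterations, logLik -514.83)
#>  covariate  level   beta    se adjusted_or ci_low ci_high p_value
#>  age_group  55-59     NA    NA          NA     NA      NA      NA
#>  age_group  60-64  0.969 0.288       2.636  1.499   4.636   0.001
#>  age_group  65-69 -0.047 0.297       0.954  0.533   1.708   0.875
#>  age_group    70+  1.267 0.293       3.549  1.997   6.306   0.000
#>  gender     Male      NA    NA          NA     NA      NA      NA
#>  gender     Female 0.563 0.212       1.757  1.159   2.663   0.008
```

Reading the output: 8.5% of the cohort is fit, 36.2% moderately and 25.3%
severely frail; the gender × severity association is significant
(p ≈ 0.012); the frail/fit odds within the female stratum are 2.23; and in
one-covariate logistic models the 70+ age group has 3.5× the frailty odds
of the 55–59 reference (here as the reference-contrast OR, 3.55).

Scoring real survey files works through the same machinery:

```r
cohort <- read_subjects("subjects.csv")   # item_1..item_30 labels and/or
cohort <- score_cohort(cohort)            #   height_m, weight_kg, sbp_mmhg, ...
run_pipeline(pipeline_config(input = "subjects.csv", output_dir = "report"))
```

`run_pipeline()` writes scored subjects, cross-tabs with chi-square, an
odds/logistic table, prevalence records with confidence intervals, a JSON
summary and a run manifest echoing every resolved cut point and the seed.

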