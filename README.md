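# phenodii

Does an inflammatory diet go with an older phenotype? `phenodii` is an
R package for epidemiologists analysing that question in complex
survey samples. It implements, end to end and fully tested:

- **PhenoAge** — phenotypic age in years from chronological age and
  nine clinical biomarkers, via a Gompertz mortality model:
  `xb = -19.907 - 0.0336·albumin + 0.0095·creatinine + 0.1953·glucose
  + 0.0954·ln(CRP) - 0.0120·lymphocyte% + 0.0268·MCV + 0.3306·RDW
  + 0.00188·ALP + 0.0554·WBC + 0.0804·age`,
  `M = 1 - exp(-1.51714·e^xb / 0.0076927)`,
  `PhenoAge = 141.50 + ln(-0.00553·ln(1-M)) / 0.09165`
  — plus the exact analytic inverse of the chain.
- **DII** — the dietary inflammatory index over 26 nutrient
  parameters, `DII = Σ w_i (2·Φ(z_i) − 1)` with z-scores against a
  global reference table, dichotomized at 0 (DII ≥ 0 is
  pro-inflammatory).
- **A design-based regression engine** — survey-weighted linear
  models with Taylor-linearized (stratum/PSU sandwich) covariance,
  t-inference on design degrees of freedom, and joint Wald tests for
  effect modification.
- **The cohort pipeline** — exclusion cascade with a counted log,
  covariate recoding, weighted descriptive table, univariate screen,
  three nested adjustment models (exposure: pro- vs anti-inflammatory
  diet), and a stratified forest across seven modifiers with one
  interaction p each.
- **A synthetic cohort generator** — NHANES-like stratified cohorts
  with *exactly* known ground truth: the true diet effect is implanted
  on PhenoAge and inverted through the scoring chain, so recovery
  tests compare against an exact truth, not an approximation.

## Worked example

```r
library(phenodii)

cfg <- generator_config(n = 2000, seed = 1, beta_diet = 0.73)
g   <- generate_cohort(cfg)          # records + per-record truth
res <- run_cohort_analysis(g$records)

res$table3
#   model  estimate        se     ci_low   ci_high         p
# 1     I 0.3390459 0.3981855 -0.5096665 1.1877582 0.4078929
# 2    II 0.2916626 0.3977383 -0.5560964 1.1394216 0.4746792
# 3   III 0.1860566 0.3171317 -0.4898935 0.8620067 0.5661404
```

Each row is one adjustment model; `estimate` is the additional years
of PhenoAge associated with a pro-inflammatory (vs anti-inflammatory)
diet, with design-based 95% CI and p. This cohort was generated with a
true effect of 0.73 y: a single n = 2,000 sample estimates it noisily,
and every model's CI covers the truth. Scoring alone:

```r
healthy40 <- data.frame(albumin = 43, creatinine = 80, glucose = 5,
  crp = 0.1, lymphocyte_pct = 30, mcv = 90, rdw = 13, alp = 70,
  wbc = 6.5, chron_age = 40)
phenoage_from_panel(healthy40)
# [1] 35.76379        — a healthy 40-year-old scores younger than 40
```

`write_results(res, "out/")` writes the exclusion log and all four
result tables as tab-delimited text; `inst/scripts/run_all.R` wraps
the same pipeline for shell use, on real delimited data via
`read_cohort()` and a column dictionary.

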