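---
title: "Dietary inflammation and phenotypic age: models, design-based inference, and the synthetic cohort"
author: "phenodii authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary inflammation and phenotypic age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodii)
```

## What the package models

`phenodii` studies whether the inflammatory potential of the diet is
associated with accelerated physiological aging in adults, using two
composite scores and a design-based inferential engine for complex
survey samples.

**Phenotypic age (PhenoAge)** is a years-scaled aging measure built from
chronological age and nine routine clinical biomarkers (albumin,
creatinine, glucose, C-reactive protein, lymphocyte percent, mean cell
volume, red-cell distribution width, alkaline phosphatase, white blood
cell count). The chain has three steps:

1. a linear predictor
   $xb = -19.907 - 0.0336\,\mathrm{alb} + 0.0095\,\mathrm{creat}
   + 0.1953\,\mathrm{glu} + 0.0954\,\ln(\mathrm{CRP})
   - 0.0120\,\mathrm{lymph} + 0.0268\,\mathrm{MCV}
   + 0.3306\,\mathrm{RDW} + 0.00188\,\mathrm{ALP}
   + 0.0554\,\mathrm{WBC} + 0.0804\,\mathrm{age}$;
2. a Gompertz 10-year mortality probability
   $M = 1 - \exp(-1.51714\, e^{xb} / 0.0076927)$;
3. the years scale
   $\mathrm{PhenoAge} = 141.50 + \ln(-0.00553 \ln(1-M)) / 0.09165$.

The scale constant satisfies $1.51714 = e^{120 \times 0.0076927} - 1$
(120 months at Gompertz rate $\gamma$), which is what identifies the
second step as a Gompertz CDF and fixes the division by $\gamma$; the
widely circulated rendering of the equation drops that operator.
Because each step is strictly monotone, the chain has an exact
analytic inverse (`invert_phenoage()`), which the synthetic generator
exploits.

Two conventions deserve emphasis. *CRP units*: the equation takes CRP
in mg/dL and logs it; supplying mg/L shifts every score by
$0.0954 \ln 10 \approx 0.22$ units of $xb$, so the unit is part of the
model, not a formality. CRP values of zero (below assay detection) are
floored at 0.01 mg/dL before the log; the floor is an argument
(`crp_floor`) everywhere it matters. *The years-scale denominator*: we
use 0.09165 by default; part of the source literature prints 0.090165.
`phenoage_constants(pheno_denom = 0.090165)` switches the whole chain,
including the inverse, with one argument.

**The dietary inflammatory index (DII)** scores one day's nutrient
intake against a global reference distribution. For nutrient $i$ with
intake $x_i$, reference mean $\mu_i$, reference SD $\sigma_i$ and
inflammatory effect score $w_i$ (positive = pro-inflammatory),

$$\mathrm{DII} = \sum_i w_i \left( 2\,\Phi\!\left(\tfrac{x_i - \mu_i}{\sigma_i}\right) - 1 \right),$$

summed over the 26 nutrient parameters used here. Missing nutrients are
skipped (contribute zero) rather than imputed — the index is defined
for fewer than its full parameter set — and the count used is reported
per record. Diets are dichotomized at zero, with the boundary in the
pro-inflammatory class (DII $\ge 0$). The packaged reference table
(`load_dii_parameters()`) is transcribed from the 2014
literature-derived DII database and carries a version tag; users doing
production work should verify the constants against the original
publication or supply their own file — every algorithmic test in the
package uses small toy tables precisely so the algorithm's correctness
does not rest on the transcription.

## Design-based inference

National examination surveys release stratified multistage samples:
strata containing (typically two) primary sampling units (PSUs), with
unequal sampling weights. The package's engine fits weighted linear
models and estimates the coefficient covariance by Taylor
linearization with the with-replacement first-stage approximation:
weighted score contributions $u_j = w_j e_j x_j$ are totalled per PSU,
the between-PSU scatter of those totals within each stratum (scaled by
$n_h/(n_h-1)$) is summed over strata, and the result is sandwiched
between $(X'WX)^{-1}$. Confidence intervals and p-values use the t
distribution with the design degrees of freedom (#PSUs − #strata), not
the normal: subgroup analyses can leave few PSUs.

Choices made where practice varies:

* **Singleton-PSU strata** (a stratum reduced to one PSU by
  subsetting) contribute their PSU total contrasted against the grand
  mean of all PSU totals, with a warning; `singleton = "fail"` turns
  this into an error. Neither silently drops the stratum.
* **Effect-modification tests** use a joint Wald test on all
  diet-by-modifier product terms ($F = W/q$ against
  $F(q, \mathrm{df} - q + 1)$), so a 3-level modifier yields one p from
  $q = 2$ product terms. A single-term test is available by calling
  `wald_test()` on one coefficient; for $q=1$ the two coincide exactly
  with the squared-t test.
* **Weight scale** is irrelevant to estimates and covariance (asserted
  to 1e-10 in the tests), which is why pooling multiple survey cycles
  only needs `combine_cycle_weights()` when population totals are
  wanted.

The engine is validated three ways: exact reduction to ordinary least
squares on degenerate designs, agreement with an independently coded
delete-one-PSU jackknife on a small instance, and 93–97% empirical
coverage of the nominal 95% interval across 500 simulated cohorts.

## The analysis pipeline

`run_cohort_analysis()` chains: covariate recoding (BMI bands at 25.0
and 30.0 kg/m²; age bands 20–39, 40–64, ≥65; smoking by the
100-lifetime-cigarettes rule; drinking by the 12-drinks rules), the
exclusion cascade, PhenoAge and DII scoring, and four outputs — the
weighted descriptive table, a univariate screen, three nested
adjustment models with `diet_class` as exposure, and a stratified
forest across seven modifiers with one interaction p each.

The exclusion cascade applies, in order: age under 20; any missing
PhenoAge biomarker; any missing nutrient; any missing covariate; and
implausible ("extreme") recall energy. "Extreme" is not standardized
anywhere authoritative; the default — below 500 kcal/day, or above
5,000 (female) / 8,000 (male) — is a widely used recall-plausibility
convention and each limit is an argument of `apply_exclusions()`.
Each step logs removed and remaining counts, and the log arithmetic is
tested.

Other pipeline conventions that were genuinely open:

* **Weighted quantiles** (the descriptive table's medians and
  quartiles) use the smallest observed value whose cumulative
  normalized weight reaches $p$ — deterministic, exactly testable, and
  reproduced by hand in the tests; an interpolating variant is a flag.
* **Adjustment sets**: Model I adjusts for continuous age and sex;
  Model II adds race and continuous BMI; Model III adds energy,
  smoking, drinking, exercise, education and the continuous
  income-to-poverty ratio. Age enters continuously (the banded version
  exists only as a stratifier); income enters continuously.
* **Stratified fits** drop the stratifier from its own adjustment set
  (and the continuous version of it, for the age and BMI bands); all
  other Model III covariates are retained. Levels that cannot support
  variance estimation are flagged in the output, never silently
  dropped.
* **Univariate screen** models are unadjusted single-predictor fits,
  with reference rows carrying no estimate.

## The synthetic cohort generator

No public-use survey file ships with the package; instead
`generate_cohort()` emits cohorts whose ground truth is *exactly*
known, so parameter-recovery tests are sharp rather than approximate.

The generator draws: 15 strata × 2 PSUs with log-normal unequal
weights (stratum base weights vary too); ages 20–85 skewed young;
covariate categories at frequencies close to the published
descriptives; and a latent diet propensity $u$ per record that drives
all 26 nutrient z-scores ($z_i = \lambda_i u + \sqrt{1-\lambda_i^2}\,
\varepsilon_i$, loading signs aligned with the inflammatory effect
scores, intakes truncated at zero). The DII and diet class are then
computed *forward* from the emitted intakes — the diet class is a
deterministic function of the nutrients, exactly as in real data. The
latent intercept is calibrated per cohort by bisection so the
pro-inflammatory fraction hits its target (default 0.5, close to the
published split).

The outcome is implanted in reverse: a target PhenoAge is assembled as
chronological age + baseline offset (−5 y) + the true diet effect +
any diet-by-age-band interaction + covariate effects + a PSU random
effect + Gaussian noise (residual SD 5 y), then pushed through the
exact inverse of the scoring chain. All biomarkers sit at fixed
healthy reference values and the red-cell distribution width absorbs
the required linear predictor (it has the largest coefficient, 0.3306
per percent, so the solved values stay in a plausible 11–18% range for
realistic targets). Implanting the effect on PhenoAge rather than on
raw biomarkers makes the true regression coefficient an exact known
quantity, not an approximation; forward-scoring the emitted panel
reproduces the target to below 1e-6 years. An optional clamping flag
(`clamp_biomarkers`) errors on targets whose solved RDW leaves a
plausible range, trading range realism for exactness explicitly rather
than silently.

The PSU random effect (SD 1 y) is not decoration: it induces
intra-cluster correlation so design-based standard errors genuinely
exceed naive ones, which is what exercises the Taylor-variance code
path. By default the latent diet factor is *independent* of the
covariates, so all three adjustment models target the same estimand
and recovery tests have an unambiguous truth; confounded variants can
be composed by the user but are not a packaged scenario.

What the generator does **not** emulate: the real survey's marginal
biomarker distributions (all but RDW are constants), the 24-hour-recall
measurement process and its recall bias, item-level correlation in
missingness (injection is independent Bernoulli per field), and any
diet–covariate confounding. Passing recovery tests therefore
demonstrates the correctness of the estimation machinery under the
stated data-generating process — not that the published point
estimates would be reproduced from the real survey files, which is out
of scope by design.

## Problem sizes and numerical choices

Simulation studies in the package use cohorts of n = 2,000 (the
default, a realistic size for method checks) with 300–500 replicates
for coverage, and n = 5,000 with 200 replicates for effect-recovery
runs, where the Monte-Carlo standard error of the mean recovered
coefficient is about 0.01 y. Recovery is judged within three
Monte-Carlo standard errors; interval coverage within 93–97%.

Numerical details: the mortality score is computed with `expm1` and
capped strictly inside (0, 1) so the downstream logs stay defined even
for extreme linear predictors; the weighted normal equations are
solved by QR with an explicit rank check that names collinear columns;
the Taylor sandwich is symmetrized against round-off; weighted
quantiles use a 1e-12 tolerance on the cumulative-weight comparison so
exact-tie fixtures are deterministic across platforms.

## A worked example

```{r example, eval = FALSE}
library(phenodii)

cfg <- generator_config(n = 2000, seed = 1, beta_diet = 0.73)
g <- generate_cohort(cfg)

res <- run_cohort_analysis(g$records)
res$table3
#   model  estimate        se     ci_low   ci_high         p
# 1     I 0.3390459 0.3981855 -0.5096665 1.1877582 0.4078929
# 2    II 0.2916626 0.3977383 -0.5560964 1.1394216 0.4746792
# 3   III 0.1860566 0.3171317 -0.4898935 0.8620067 0.5661404

res$forest[res$forest$stratifier == "age_group", ]
write_results(res, "results")
```

The Model III row is the headline association: years of additional
PhenoAge for a pro-inflammatory versus anti-inflammatory diet, with a
design-based 95% CI and t-test p on 15 design df. (The cohort above
was generated with a true effect of 0.73 y and no interaction; a
single cohort of 2,000 estimates it noisily — every model's CI covers
the truth — and the recovery runs over 200 replicates of 5,000 pin the
mean estimate to it within Monte-Carlo error.)

## Known limitations

* The DII reference constants are a transcription; the packaged file
  is versioned and replaceable, and no correctness claim in the test
  suite depends on it.
* The engine covers linear models with Taylor variance only — no
  replicate-weight (BRR/Fay) variance, no logistic/Cox outcomes, no
  finite-population corrections.
* PhenoAge is treated strictly as a continuous outcome; the package
  does not re-estimate its coefficients or model age-acceleration
  residuals (`phenoage_accel` is exposed as a convenience column
  only).
* Real-data ingestion expects delimited text through the column
  dictionary; SAS transport conversion is left to the user's tooling.
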