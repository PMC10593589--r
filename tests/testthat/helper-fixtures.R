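# Shared fixtures and independent oracles.

# Healthy 40-year-old reference panel; chain values frozen from a
# term-by-term closed-form evaluation done independently of the package.
fixture_panel <- function() {
  data.frame(albumin = 43, creatinine = 80, glucose = 5, crp = 0.1,
             lymphocyte_pct = 30, mcv = 90, rdw = 13, alp = 70,
             wbc = 6.5, chron_age = 40)
}
FIX_XB <- -9.77746661787163
FIX_M <- 0.0111229625165769
FIX_PHENOAGE <- 35.7637900049542

random_panels <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    albumin = runif(n, 35, 50), creatinine = runif(n, 50, 110),
    glucose = runif(n, 4, 8), crp = runif(n, 0.02, 1),
    lymphocyte_pct = runif(n, 15, 45), mcv = runif(n, 80, 100),
    rdw = runif(n, 11, 16), alp = runif(n, 40, 120),
    wbc = runif(n, 4, 11), chron_age = runif(n, 20, 85))
}

toy_dii_params <- function() {
  data.frame(name = c("A", "B"), unit = "g",
             global_mean = c(10, 1), global_sd = c(2, 1),
             effect_score = c(-0.5, 0.4))
}

# 12-record, 3-stratum, 2-PSUs-per-stratum toy survey dataset with
# mildly unequal weights and covariate values spread across PSUs (kept
# well-conditioned: at this size the linearized and jackknife variances
# agree only for reasonably balanced instances).
toy_survey_data <- function(seed = 2) {
  set.seed(seed)
  d <- data.frame(
    stratum = rep(1:3, each = 4),
    psu = rep(rep(1:2, each = 2), 3),
    weight = round(runif(12, 0.8, 1.4), 2),
    x = rep(c(2, 5, 8, 4, 7, 3), 2))
  d$y <- round(1 + 0.5 * d$x + rnorm(12, 0, 0.6), 2)
  d
}

# Independent delete-one-PSU jackknife (JKn) covariance oracle: refits
# with each PSU removed and its stratum mates reweighted by nh/(nh-1).
jackknife_vcov <- function(x, y, d) {
  x <- as.matrix(x)
  full <- phenodii::weighted_ls(x, y, d$weight)
  psus <- unique(d[c("stratum", "psu")])
  v <- matrix(0, ncol(x), ncol(x))
  for (h in unique(psus$stratum)) {
    ph <- psus$psu[psus$stratum == h]
    nh <- length(ph)
    for (p in ph) {
      keep <- !(d$stratum == h & d$psu == p)
      w <- d$weight[keep]
      w[d$stratum[keep] == h] <- w[d$stratum[keep] == h] * nh / (nh - 1)
      b <- phenodii::weighted_ls(x[keep, , drop = FALSE], y[keep], w)
      v <- v + (nh - 1) / nh * tcrossprod(b - full)
    }
  }
  v
}

# Model formulas of the three adjustment sets.
model_formula <- function(model = c("I", "II", "III")) {
  model <- match.arg(model)
  covs <- switch(model,
    I = "chron_age + sex",
    II = "chron_age + sex + race + bmi",
    III = paste("chron_age + sex + race + bmi + energy + smoking +",
                "drinking + exercise + education + income_poverty_ratio"))
  stats::as.formula(paste("phenoage ~ diet_class +", covs))
}

# Generate, score and wrap one synthetic cohort for model fitting.
scored_cohort <- function(config, seed) {
  g <- phenodii::generate_cohort(config, seed = seed)
  d <- phenodii::score_dii(phenodii::score_phenoage(
    phenodii::recode_covariates(g$records)))
  list(data = d,
       design = phenodii::survey_design(d$stratum, d$psu, d$weight),
       truth = g$truth)
}

# Hand-countable raw cohort for the exclusion cascade: 10 records, of
# which 2 are under 20, one (of the adults) is missing albumin, and one
# adult male reports 12,000 kcal.
exclusion_fixture <- function() {
  g <- phenodii::generate_cohort(phenodii::generator_config(n = 10,
                                                            seed = 5))
  d <- phenodii::recode_covariates(g$records)
  d$chron_age[c(1, 2)] <- c(17, 19)
  d$albumin[3] <- NA
  d$sex[4] <- "male"
  d$energy[4] <- 12000
  d
}
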