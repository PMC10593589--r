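#' Configuration of the synthetic cohort generator
#'
#' All true parameters of the simulated cohort. Defaults emulate an
#' NHANES-like adult sample: a stratified design with two PSUs per
#' stratum and unequal log-normal weights, ages 20-85 skewed young,
#' covariate category frequencies close to the published descriptive
#' table, a latent diet-quality factor driving correlated nutrient
#' intakes, and a configurable true effect of a pro-inflammatory diet on
#' PhenoAge with an optional extra effect per older age band.
#'
#' @param n Cohort size (default 2000, a realistic simulation-study size).
#' @param seed Integer seed; every random draw is governed by it.
#' @param n_strata,psus_per_stratum Design shape (defaults 15 and 2).
#' @param weight_sdlog Log-normal sd of record weights within a stratum;
#'   stratum base weights vary too, so weights are genuinely unequal.
#' @param pro_fraction Target fraction of pro-inflammatory diets; the
#'   latent-factor intercept is calibrated per cohort to hit it. Ignored
#'   when `u_mean` is supplied.
#' @param u_mean Optional fixed intercept of the latent diet propensity.
#' @param loading Magnitude of each nutrient's loading on the latent
#'   factor; the sign is aligned with the nutrient's inflammatory effect
#'   score, so higher latent values mean more pro-inflammatory intakes.
#' @param alpha0 Baseline offset of PhenoAge from chronological age
#'   (years).
#' @param beta_diet True effect of a pro-inflammatory diet on PhenoAge
#'   (years).
#' @param beta_age_interaction Additional diet effect per older age band
#'   (0 for ages 20-39, 1 for 40-64, 2 for 65+), in years per band.
#' @param covariate_effects Named numeric vector of true covariate
#'   effects on PhenoAge (see defaults in the function body); set to
#'   `zero_covariate_effects()` for a confounder-free cohort.
#' @param residual_sd Residual sd of PhenoAge (years).
#' @param psu_sd Sd of the PSU-level random effect (years); non-zero so
#'   design-based standard errors genuinely exceed naive ones.
#' @param missing_rates Named list of per-field missingness rates for
#'   [inject_missingness()].
#' @param clamp_biomarkers If `TRUE`, targets whose required red-cell
#'   distribution width falls outside `rdw_range` raise an error instead
#'   of being emitted (exactness is never traded silently for realism).
#' @param rdw_range Plausible RDW range used when clamping (percent).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n = 2000, seed = 1L, n_strata = 15L,
                             psus_per_stratum = 2L, weight_sdlog = 0.6,
                             pro_fraction = 0.5, u_mean = NULL,
                             loading = 0.5, alpha0 = -5,
                             beta_diet = 0.73, beta_age_interaction = 0,
                             covariate_effects = default_covariate_effects(),
                             residual_sd = 5, psu_sd = 1,
                             missing_rates = list(),
                             clamp_biomarkers = FALSE,
                             rdw_range = c(9, 25)) {
  stopifnot(n >= 1, n_strata >= 1, psus_per_stratum >= 1,
            residual_sd >= 0, psu_sd >= 0, weight_sdlog >= 0,
            loading >= 0, loading < 1)
  if (!is.null(pro_fraction))
    stopifnot(pro_fraction > 0, pro_fraction < 1)
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              n_strata = as.integer(n_strata),
              psus_per_stratum = as.integer(psus_per_stratum),
              weight_sdlog = weight_sdlog, pro_fraction = pro_fraction,
              u_mean = u_mean, loading = loading, alpha0 = alpha0,
              beta_diet = beta_diet,
              beta_age_interaction = beta_age_interaction,
              covariate_effects = covariate_effects,
              residual_sd = residual_sd, psu_sd = psu_sd,
              missing_rates = missing_rates,
              clamp_biomarkers = isTRUE(clamp_biomarkers),
              rdw_range = rdw_range,
              sex_p_male = 0.494, race_p_white = 0.511,
              education_probs = c(0.284, 0.239, 0.477),
              exercise_probs = c(0.481, 0.268, 0.251),
              smoking_probs = c(0.519, 0.269, 0.212),
              drinking_probs = c(0.133, 0.388, 0.479))
  for (p in c("education_probs", "exercise_probs", "smoking_probs",
              "drinking_probs"))
    if (abs(sum(cfg[[p]]) - 1) > 1e-8)
      stop(p, " must sum to 1", call. = FALSE)
  class(cfg) <- "generator_config"
  cfg
}

#' True covariate effects used by the default generator
#'
#' Years of PhenoAge per unit (continuous) or relative to the reference
#' level (categorical). Directions follow the epidemiological literature:
#' obesity, smoking history and low education age the phenotype; exercise
#' is protective.
#' @return Named numeric vector.
#' @export
default_covariate_effects <- function() {
  c(sex_male = -0.8, race_other = -2.0, bmi = 0.3, energy = -5e-04,
    smoking_former = 2.0, smoking_current = 1.0,
    drinking_former = -1.0, drinking_current = -1.5,
    exercise_moderate = -1.0, exercise_vigorous = -3.0,
    education_high_school = -0.5, education_college_or_above = -1.5,
    income_poverty_ratio = 0.1)
}

#' All-zero covariate effects (confounder-free cohorts)
#' @return Named numeric vector of zeros matching
#'   [default_covariate_effects()].
#' @export
zero_covariate_effects <- function() {
  e <- default_covariate_effects()
  e[] <- 0
  e
}

# DII from latent z-scores with truncation at zero intake:
# intake = max(0, mean + sd*z)  <=>  effective z = max(z, -mean/sd)
dii_from_z <- function(z, params) {
  zt <- pmax(z, rep(-params$global_mean / params$global_sd,
                    each = nrow(z)))
  rowSums((2 * stats::pnorm(zt) - 1) *
            rep(params$effect_score, each = nrow(z)))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws design labels and weights, demographics and covariates, then a
#' latent diet propensity per record that drives correlated nutrient
#' z-scores (`z_i = lambda_i * u + sqrt(1 - lambda_i^2) * eps_i`, intakes
#' truncated at zero). The DII and diet class are computed forward from
#' the emitted intakes. The true target PhenoAge is assembled as
#' chronological age plus the baseline offset, the diet effect, any
#' diet-by-age-band interaction, covariate effects, a PSU random effect
#' and Gaussian noise — then inverted *exactly* through the PhenoAge
#' equations: all biomarkers sit at fixed healthy reference values and
#' the red-cell distribution width absorbs the required linear-predictor
#' value (its coefficient is the largest, keeping values plausible).
#' Forward-scoring the emitted biomarkers therefore reproduces the true
#' target to machine precision, making the true regression coefficients
#' exactly known.
#'
#' @param config A [generator_config()].
#' @param seed Optional override of `config$seed`.
#' @return List with `records` (raw participant table, ready for
#'   [run_cohort_analysis()]) and `truth` (per-record latent propensity
#'   `u`, `diet_pro`, `age_band`, `target_phenoage`, `xb`), plus
#'   `u_shift`, the calibrated latent intercept.
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL) {
  if (!inherits(config, "generator_config"))
    stop("config must come from generator_config()", call. = FALSE)
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n <- config$n
  params <- load_dii_parameters()

  ## design
  stratum <- sample.int(config$n_strata, n, replace = TRUE)
  psu <- sample.int(config$psus_per_stratum, n, replace = TRUE)
  stratum_base <- exp(stats::rnorm(config$n_strata, 0, 0.3))
  weight <- stats::rlnorm(n, log(stratum_base[stratum]),
                          config$weight_sdlog)
  psu_effect_tab <- matrix(
    stats::rnorm(config$n_strata * config$psus_per_stratum, 0,
                 config$psu_sd),
    config$n_strata, config$psus_per_stratum)
  psu_effect <- psu_effect_tab[cbind(stratum, psu)]

  ## demographics and covariates
  chron_age <- 20 + 65 * stats::rbeta(n, 1.1, 1.5)
  sex <- factor(ifelse(stats::runif(n) < config$sex_p_male, "male",
                       "female"), levels = c("female", "male"))
  race <- factor(ifelse(stats::runif(n) < config$race_p_white,
                        "non_hispanic_white", "other"),
                 levels = c("non_hispanic_white", "other"))
  education <- factor(sample(c("under_high_school", "high_school",
                               "college_or_above"), n, TRUE,
                             config$education_probs),
                      levels = c("under_high_school", "high_school",
                                 "college_or_above"))
  exercise <- factor(sample(c("inactive", "moderate", "vigorous"), n,
                            TRUE, config$exercise_probs),
                     levels = c("inactive", "moderate", "vigorous"))
  smoking <- factor(sample(c("non", "former", "current"), n, TRUE,
                           config$smoking_probs),
                    levels = c("non", "former", "current"))
  drinking <- factor(sample(c("non", "former", "current"), n, TRUE,
                            config$drinking_probs),
                     levels = c("non", "former", "current"))
  income_poverty_ratio <- pmin(5, stats::rlnorm(n, log(2.8), 0.7))
  bmi <- stats::rlnorm(n, log(27.3), 0.18)
  energy <- stats::rlnorm(n, ifelse(sex == "male", log(2400), log(1800)),
                          0.33)

  ## latent diet propensity and nutrient intakes
  lambda <- config$loading * sign(params$effect_score)
  lambda[lambda == 0] <- config$loading
  u0 <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * nrow(params)), n, nrow(params))
  z_of <- function(shift)
    outer(u0 + shift, lambda) +
      sweep(eps, 2L, sqrt(1 - lambda^2), "*")
  if (!is.null(config$u_mean)) {
    shift <- config$u_mean
  } else {
    lo <- -10; hi <- 10
    for (k in 1:30) {
      mid <- (lo + hi) / 2
      frac <- mean(dii_from_z(z_of(mid), params) >= 0)
      if (frac < config$pro_fraction) lo <- mid else hi <- mid
    }
    shift <- (lo + hi) / 2
  }
  z <- z_of(shift)
  intakes <- pmax(sweep(sweep(z, 2L, params$global_sd, "*"), 2L,
                        params$global_mean, "+"), 0)
  colnames(intakes) <- params$name
  dii <- dii_score(as.data.frame(intakes), params)$dii
  pro <- as.integer(dii >= 0)

  ## true outcome and exact biomarker inversion
  age_band <- findInterval(chron_age, c(40, 65))   # 0, 1, 2
  ce <- config$covariate_effects
  cov_term <-
    ce[["sex_male"]] * (sex == "male") +
    ce[["race_other"]] * (race == "other") +
    ce[["bmi"]] * bmi +
    ce[["energy"]] * energy +
    ce[["smoking_former"]] * (smoking == "former") +
    ce[["smoking_current"]] * (smoking == "current") +
    ce[["drinking_former"]] * (drinking == "former") +
    ce[["drinking_current"]] * (drinking == "current") +
    ce[["exercise_moderate"]] * (exercise == "moderate") +
    ce[["exercise_vigorous"]] * (exercise == "vigorous") +
    ce[["education_high_school"]] * (education == "high_school") +
    ce[["education_college_or_above"]] * (education == "college_or_above") +
    ce[["income_poverty_ratio"]] * income_poverty_ratio
  target <- chron_age + config$alpha0 +
    config$beta_diet * pro +
    config$beta_age_interaction * age_band * pro +
    cov_term + psu_effect + stats::rnorm(n, 0, config$residual_sd)

  cons <- phenoage_constants()
  xb_needed <- invert_phenoage(target, cons)
  ref <- c(albumin = 43, creatinine = 80, glucose = 5, crp = 0.1,
           lymphocyte_pct = 30, mcv = 90, alp = 70, wbc = 6.5)
  k <- cons$coefs
  xb_no_rdw <- cons$intercept_xb +
    k[["albumin"]] * ref[["albumin"]] +
    k[["creatinine"]] * ref[["creatinine"]] +
    k[["glucose"]] * ref[["glucose"]] +
    k[["log_crp"]] * log(ref[["crp"]]) +
    k[["lymphocyte_pct"]] * ref[["lymphocyte_pct"]] +
    k[["mcv"]] * ref[["mcv"]] +
    k[["alp"]] * ref[["alp"]] +
    k[["wbc"]] * ref[["wbc"]] +
    k[["chron_age"]] * chron_age
  rdw <- (xb_needed - xb_no_rdw) / k[["rdw"]]
  if (config$clamp_biomarkers) {
    bad <- which(rdw < config$rdw_range[1] | rdw > config$rdw_range[2])
    if (length(bad))
      stop("target PhenoAge unachievable within the plausible RDW range ",
           "for record(s): ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }

  records <- data.frame(
    id = seq_len(n), chron_age = chron_age, sex = sex, race = race,
    education = education, income_poverty_ratio = income_poverty_ratio,
    exercise = exercise, smoking = smoking, drinking = drinking,
    bmi = bmi, energy = energy,
    albumin = ref[["albumin"]], creatinine = ref[["creatinine"]],
    glucose = ref[["glucose"]], crp = ref[["crp"]],
    lymphocyte_pct = ref[["lymphocyte_pct"]], mcv = ref[["mcv"]],
    rdw = rdw, alp = ref[["alp"]], wbc = ref[["wbc"]],
    stratum = stratum, psu = psu, weight = weight)
  records <- cbind(records, as.data.frame(intakes))

  truth <- data.frame(id = seq_len(n), u = u0 + shift, dii = dii,
                      diet_pro = pro, age_band = age_band,
                      target_phenoage = target, xb = xb_needed)
  list(records = records, truth = truth, u_shift = shift)
}

#' Mask fields at random to exercise the exclusion cascade
#'
#' Independently sets each configured field to `NA` with its Bernoulli
#' rate. Reproducible given the seed.
#'
#' @param records Participant data.frame.
#' @param rates Named list/vector of per-field rates in `[0, 1)`.
#' @param seed Integer seed.
#' @return `records` with missing values injected.
#' @export
inject_missingness <- function(records, rates, seed = 1L) {
  if (!length(rates)) return(records)
  rates <- unlist(rates)
  if (any(rates < 0 | rates >= 1))
    stop("missingness rates must lie in [0, 1)", call. = FALSE)
  miss <- setdiff(names(rates), names(records))
  if (length(miss))
    stop("unknown field(s) in missingness rates: ",
         paste(miss, collapse = ", "), call. = FALSE)
  set.seed(as.integer(seed))
  for (f in names(rates)) {
    mask <- stats::runif(nrow(records)) < rates[[f]]
    records[[f]][mask] <- NA
  }
  records
}
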