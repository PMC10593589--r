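covariate_names <- function() {
  c("sex", "race", "education", "income_poverty_ratio", "exercise",
    "smoking", "drinking", "bmi", "energy")
}

model_covariates <- function(model = c("I", "II", "III")) {
  model <- match.arg(model)
  base <- c("chron_age", "sex")
  if (model == "I") return(base)
  two <- c(base, "race", "bmi")
  if (model == "II") return(two)
  c(two, "energy", "smoking", "drinking", "exercise", "education",
    "income_poverty_ratio")
}

forest_stratifiers <- function() {
  c("sex", "age_group", "race", "exercise", "smoking", "drinking",
    "bmi_group")
}

#' Derive the analysis categories from raw covariates
#'
#' Adds `bmi_group` (`<25.0`, `25.0-29.9`, `>=30.0` kg/m^2), `age_group`
#' (20-39, 40-64, >=65 years) and, when the raw instrument fields are
#' present, the three-level smoking and drinking statuses:
#'
#' * smoking — non-smoker if fewer than 100 lifetime cigarettes; former if
#'   at least 100 but none per day in the past 30 days; current otherwise
#'   (requires columns `cigs_lifetime` and `cigs_per_day_30d`).
#' * drinking — current if at least 12 drinks in the past year and a
#'   non-zero weekly amount; former if at least 12 lifetime drinks but
#'   fewer than 12 in the past year; non-drinker otherwise (requires
#'   `drinks_lifetime`, `drinks_past_year`, `drinks_per_week`).
#'
#' If the raw fields are absent, existing `smoking` / `drinking` columns
#' with levels `non`, `former`, `current` are kept as-is. Unclassifiable
#' values (missing raw fields for a record) become `NA` and are removed
#' later by the missing-covariate exclusion step.
#'
#' @param records Participant data.frame.
#' @return `records` with the derived factor columns appended/overwritten.
#' @export
recode_covariates <- function(records) {
  if (!is.null(records$bmi))
    records$bmi_group <- cut(records$bmi, c(-Inf, 25, 30, Inf),
                             labels = c("<25.0", "25.0-29.9", ">=30.0"),
                             right = FALSE)
  if (!is.null(records$chron_age))
    records$age_group <- cut(records$chron_age, c(-Inf, 40, 65, Inf),
                             labels = c("20-39", "40-64", ">=65"),
                             right = FALSE)
  if (all(c("cigs_lifetime", "cigs_per_day_30d") %in% names(records))) {
    records$smoking <- factor(
      ifelse(records$cigs_lifetime < 100, "non",
             ifelse(records$cigs_per_day_30d > 0, "current", "former")),
      levels = c("non", "former", "current"))
  } else if (!is.null(records$smoking)) {
    records$smoking <- factor(records$smoking,
                              levels = c("non", "former", "current"))
  }
  if (all(c("drinks_lifetime", "drinks_past_year", "drinks_per_week") %in%
          names(records))) {
    records$drinking <- factor(
      ifelse(records$drinks_past_year >= 12 & records$drinks_per_week > 0,
             "current",
             ifelse(records$drinks_lifetime >= 12 &
                      records$drinks_past_year < 12, "former", "non")),
      levels = c("non", "former", "current"))
  } else if (!is.null(records$drinking)) {
    records$drinking <- factor(records$drinking,
                               levels = c("non", "former", "current"))
  }
  for (v in c("sex", "race", "education", "exercise"))
    if (!is.null(records[[v]]) && !is.factor(records[[v]]))
      records[[v]] <- factor(records[[v]], levels = switch(
        v,
        sex = c("female", "male"),
        race = c("non_hispanic_white", "other"),
        education = c("under_high_school", "high_school",
                      "college_or_above"),
        exercise = c("inactive", "moderate", "vigorous")))
  records
}

#' Sequential exclusion cascade
#'
#' Applies the analysis eligibility filters in order, logging the count
#' removed at every step:
#'
#' 1. `age_under_20` — chronological age missing or below 20;
#' 2. `missing_biomarker` — any of the nine PhenoAge biomarkers missing;
#' 3. `missing_diet` — any nutrient intake missing;
#' 4. `missing_covariate` — any adjustment covariate missing (sex, race,
#'    education, income ratio, exercise, smoking, drinking, BMI, energy);
#' 5. `extreme_diet` — implausible recall: daily energy below
#'    `energy_min` kcal, or above `energy_max_female` / `energy_max_male`.
#'
#' @param records Participant data.frame (after [recode_covariates()]).
#' @param energy_min,energy_max_female,energy_max_male Plausibility limits
#'   in kcal/day; defaults 500, 5000, 8000.
#' @return List with `records` (rows surviving all filters) and `log`, a
#'   data.frame with columns `step`, `removed`, `remaining`.
#' @export
apply_exclusions <- function(records, energy_min = 500,
                             energy_max_female = 5000,
                             energy_max_male = 8000) {
  nutr <- intersect(load_dii_parameters()$name, names(records))
  bio <- intersect(c(biomarker_names()), names(records))
  cov <- intersect(covariate_names(), names(records))
  drop_by <- list(
    age_under_20 = function(d)
      is.na(d$chron_age) | d$chron_age < 20,
    missing_biomarker = function(d)
      if (length(bio)) rowSums(is.na(d[bio])) > 0 else rep(TRUE, nrow(d)),
    missing_diet = function(d)
      if (length(nutr)) rowSums(is.na(d[nutr])) > 0 else rep(TRUE, nrow(d)),
    missing_covariate = function(d)
      if (length(cov)) rowSums(is.na(d[cov])) > 0 else rep(TRUE, nrow(d)),
    extreme_diet = function(d)
      d$energy < energy_min |
        (d$sex == "female" & d$energy > energy_max_female) |
        (d$sex == "male" & d$energy > energy_max_male)
  )
  log <- data.frame(step = names(drop_by), removed = NA_integer_,
                    remaining = NA_integer_)
  for (i in seq_along(drop_by)) {
    bad <- drop_by[[i]](records)
    bad[is.na(bad)] <- TRUE
    records <- records[!bad, , drop = FALSE]
    log$removed[i] <- sum(bad)
    log$remaining[i] <- nrow(records)
    if (nrow(records) == 0L)
      stop("no records remain after exclusion step '", names(drop_by)[i],
           "'", call. = FALSE)
  }
  list(records = records, log = log)
}

#' Weighted quantile
#'
#' Default convention: the smallest observed value whose cumulative
#' normalized weight reaches `p` (a left-continuous inverse, no
#' interpolation) — deterministic and exactly testable. With
#' `interpolate = TRUE`, linear interpolation between the bracketing
#' order statistics on the cumulative-weight scale is used instead.
#'
#' @param values Numeric vector (non-empty).
#' @param weights Positive weights, same length.
#' @param p Probabilities in (0, 1).
#' @param interpolate Use the interpolating variant.
#' @return Quantile value(s), one per element of `p`.
#' @export
weighted_quantile <- function(values, weights, p, interpolate = FALSE) {
  if (!length(values) || length(values) != length(weights))
    stop("values and weights must be non-empty and of equal length",
         call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  if (any(p <= 0 | p >= 1))
    stop("p must lie strictly in (0, 1)", call. = FALSE)
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  vapply(p, function(pp) {
    if (interpolate) {
      stats::approx(cw, v, xout = pp, rule = 2, ties = "ordered")$y
    } else {
      v[which(cw >= pp - 1e-12)[1L]]
    }
  }, numeric(1))
}

#' Weighted descriptive table by diet class
#'
#' Continuous variables are summarized as the weighted median (25th, 75th
#' percentile); categorical variables as unweighted count plus weighted
#' percentage — overall and within each diet class. Percentages within a
#' variable sum to 100 in every column.
#'
#' @param records Analysis-ready data.frame with derived fields
#'   (`diet_class`, `bmi_group`, `age_group`, `phenoage`, ...).
#' @param design A `svy_design` aligned with `records`.
#' @param continuous,categorical Variable name vectors; defaults cover the
#'   standard descriptive set (variables absent from `records` are
#'   skipped).
#' @return Long-format data.frame: `variable`, `level` (`NA` for
#'   continuous rows), `group` (total / anti_inflammatory /
#'   pro_inflammatory), `n`, `weighted_pct`, `median`, `p25`, `p75`.
#' @export
build_table1 <- function(records, design,
                         continuous = c("chron_age",
                                        "income_poverty_ratio", "bmi",
                                        "energy", "phenoage"),
                         categorical = c("sex", "race", "age_group",
                                         "education", "exercise",
                                         "smoking", "drinking",
                                         "bmi_group")) {
  if (is.null(records$diet_class) || any(table(records$diet_class) == 0L))
    stop("both diet classes must be populated", call. = FALSE)
  w <- design$weights
  groups <- list(total = rep(TRUE, nrow(records)),
                 anti_inflammatory = records$diet_class == "anti_inflammatory",
                 pro_inflammatory = records$diet_class == "pro_inflammatory")
  rows <- list()
  for (v in intersect(continuous, names(records))) {
    for (g in names(groups)) {
      i <- groups[[g]]
      q <- weighted_quantile(records[[v]][i], w[i], c(0.5, 0.25, 0.75))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, group = g, n = sum(i),
        weighted_pct = NA_real_, median = q[1], p25 = q[2], p75 = q[3])
    }
  }
  for (v in intersect(categorical, names(records))) {
    f <- factor(records[[v]])
    for (g in names(groups)) {
      i <- groups[[g]]
      tot_w <- sum(w[i])
      for (lev in levels(f)) {
        j <- i & f == lev
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev, group = g, n = sum(j),
          weighted_pct = 100 * sum(w[j]) / tot_w,
          median = NA_real_, p25 = NA_real_, p75 = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Univariate screen of candidate predictors
#'
#' Fits one single-predictor survey-weighted model of PhenoAge per
#' variable. Categorical predictors contribute one row per non-reference
#' level (reference rows carry no estimate); continuous predictors one
#' row.
#'
#' @param records Analysis-ready data.frame.
#' @param design A `svy_design` aligned with `records`.
#' @param variables Predictors to screen; defaults to the standard set.
#' @param level Confidence level.
#' @return Data.frame: `variable`, `level`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p` (reference rows all `NA` with `level` marked
#'   `"Reference"` suffix-free).
#' @export
run_univariate <- function(records, design,
                           variables = c("diet_class", "sex", "race",
                                         "chron_age", "age_group",
                                         "education",
                                         "income_poverty_ratio",
                                         "exercise", "smoking", "drinking",
                                         "bmi", "bmi_group", "energy"),
                           level = 0.95) {
  rows <- list()
  for (v in intersect(variables, names(records))) {
    fit <- fit_survey_model(stats::reformulate(v, "phenoage"), records,
                            design, level = level)
    x <- records[[v]]
    if (is.factor(x)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = levels(x)[1L], estimate = NA_real_,
        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_)
      for (lev in levels(x)[-1L]) {
        r <- fit$table[fit$table$term == paste0(v, lev), ]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev, estimate = r$estimate, se = r$se,
          ci_low = r$ci_low, ci_high = r$ci_high, p = r$p)
      }
    } else {
      r <- fit$table[fit$table$term == v, ]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, estimate = r$estimate,
        se = r$se, ci_low = r$ci_low, ci_high = r$ci_high, p = r$p)
    }
  }
  do.call(rbind, rows)
}

#' Adjusted models of dietary inflammation on PhenoAge
#'
#' Fits the three nested adjustment sets with `diet_class` as the
#' exposure:
#' * Model I — age (years) and sex;
#' * Model II — Model I plus race and BMI;
#' * Model III — Model II plus energy intake, smoking, drinking, physical
#'   exercise, education and income-to-poverty ratio.
#'
#' @param records Analysis-ready data.frame.
#' @param design A `svy_design` aligned with `records`.
#' @param level Confidence level.
#' @return List with `fits` (the three `svy_fit`s, named I/II/III) and
#'   `table`: one row per model with the pro- vs anti-inflammatory
#'   estimate, CI and p.
#' @export
run_adjusted_models <- function(records, design, level = 0.95) {
  fits <- list()
  rows <- list()
  for (m in c("I", "II", "III")) {
    f <- stats::reformulate(c("diet_class", model_covariates(m)),
                            "phenoage")
    fit <- fit_survey_model(f, records, design, level = level)
    fits[[m]] <- fit
    r <- fit$table[fit$table$term == "diet_classpro_inflammatory", ]
    rows[[m]] <- data.frame(model = m, estimate = r$estimate, se = r$se,
                            ci_low = r$ci_low, ci_high = r$ci_high, p = r$p)
  }
  list(fits = fits, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Stratified analysis with interaction tests
#'
#' For each stratifier (sex, age group, race, exercise, smoking,
#' drinking, BMI group): the fully adjusted model is refitted within each
#' level, dropping the stratifier itself from the adjustment set (and,
#' for age group, also dropping continuous age, since the level is an age
#' band); one interaction p per stratifier comes from adding
#' diet-by-stratifier product terms to the full-data adjusted model and
#' testing them jointly by Wald.
#'
#' Levels whose subset lacks the design df for variance estimation are
#' flagged (`flag` column) rather than silently dropped.
#'
#' @param records Analysis-ready data.frame.
#' @param design A `svy_design` aligned with `records`.
#' @param stratifiers Stratifier names; default the standard seven.
#' @param level Confidence level.
#' @param singleton Singleton-PSU rule for subset fits, see
#'   [taylor_covariance()].
#' @return Data.frame: `stratifier`, `level`, `n`, `estimate`, `ci_low`,
#'   `ci_high`, `p`, `p_interaction` (shared across a stratifier's rows),
#'   `flag`.
#' @export
stratified_forest <- function(records, design,
                              stratifiers = forest_stratifiers(),
                              level = 0.95,
                              singleton = c("centre", "fail")) {
  singleton <- match.arg(singleton)
  rows <- list()
  for (s in intersect(stratifiers, names(records))) {
    covs <- setdiff(model_covariates("III"), s)
    if (s == "age_group") covs <- setdiff(covs, "chron_age")
    if (s == "bmi_group") covs <- setdiff(covs, "bmi")
    int_fit <- fit_survey_model(
      stats::as.formula(paste("phenoage ~ diet_class +",
                              paste(model_covariates("III"),
                                    collapse = " + "),
                              "+", s, "+ diet_class:", s)),
      records, design, level = level, singleton = singleton)
    prod_terms <- grep("^diet_classpro_inflammatory:",
                       names(stats::coef(int_fit)), value = TRUE)
    p_int <- wald_test(int_fit, prod_terms)$p
    f_level <- factor(records[[s]])
    for (lev in levels(f_level)) {
      i <- which(f_level == lev)
      row <- data.frame(stratifier = s, level = lev, n = length(i),
                        estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        p_interaction = p_int, flag = "")
      fit_l <- tryCatch(
        withCallingHandlers(
          fit_survey_model(stats::reformulate(c("diet_class", covs),
                                              "phenoage"),
                           droplevels(records[i, , drop = FALSE]),
                           subset_design(design, i), level = level,
                           singleton = singleton),
          warning = function(w) {
            row$flag <<- conditionMessage(w)
            invokeRestart("muffleWarning")
          }),
        error = function(e) e)
      if (inherits(fit_l, "error")) {
        row$flag <- conditionMessage(fit_l)
      } else {
        r <- fit_l$table[fit_l$table$term == "diet_classpro_inflammatory", ]
        row$estimate <- r$estimate
        row$ci_low <- r$ci_low
        row$ci_high <- r$ci_high
        row$p <- r$p
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' End-to-end cohort analysis
#'
#' Runs the whole pipeline on a raw participant table: covariate
#' recoding, the exclusion cascade, PhenoAge and DII scoring, then the
#' weighted descriptive table, the univariate screen, the three adjusted
#' models and the stratified forest with interaction tests. Deterministic:
#' the same input yields byte-identical outputs.
#'
#' @param records Raw participant data.frame with the canonical columns
#'   (see [default_column_dictionary()]); must include `stratum`, `psu`,
#'   `weight`.
#' @param dii_params DII parameter table.
#' @param constants PhenoAge constant set.
#' @param crp_floor CRP floor (mg/dL).
#' @param level Confidence level.
#' @return List: `records` (analysis-ready, scored), `design`,
#'   `exclusion_log`, `table1`, `table2` (univariate), `table3` (adjusted
#'   models), `forest`, `meta` (parameter-table version etc.).
#' @export
run_cohort_analysis <- function(records, dii_params = load_dii_parameters(),
                                constants = phenoage_constants(),
                                crp_floor = 0.01, level = 0.95) {
  records <- recode_covariates(records)
  excl <- apply_exclusions(records)
  d <- excl$records
  d <- score_phenoage(d, constants, crp_floor)
  d <- score_dii(d, dii_params)
  design <- survey_design(d$stratum, d$psu, d$weight)
  adj <- run_adjusted_models(d, design, level = level)
  list(records = d,
       design = design,
       exclusion_log = excl$log,
       table1 = build_table1(d, design),
       table2 = run_univariate(d, design, level = level),
       table3 = adj$table,
       fits = adj$fits,
       forest = stratified_forest(d, design, level = level),
       meta = data.frame(
         key = c("n_analysis", "dii_table_version", "crp_floor_mg_dl",
                 "confidence_level"),
         value = c(nrow(d), attr(dii_params, "version"), crp_floor, level)))
}
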