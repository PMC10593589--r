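test_that("weighted least squares solves the normal equations", {
  x <- cbind(intercept = 1, x = c(0, 1, 2))
  expect_equal(unname(weighted_ls(x, c(0, 1, 2), rep(1, 3))), c(0, 1),
               tolerance = 1e-12)
  # hand/oracle solution of the 2x2 weighted system
  b <- weighted_ls(x, c(0, 1, 1), c(1, 1, 2))
  expect_equal(unname(b), c(2 / 11, 5 / 11), tolerance = 1e-12)
  # equal weights reduce to ordinary least squares
  set.seed(1)
  xx <- cbind(1, rnorm(40), runif(40))
  colnames(xx) <- c("(Intercept)", "a", "b")
  yy <- rnorm(40)
  expect_equal(unname(weighted_ls(xx, yy, rep(2.5, 40))),
               unname(coef(lm.fit(xx, yy))), tolerance = 1e-10)
  # rank deficiency names the collinear column
  x_bad <- cbind(one = 1, z = 1:4, z2 = 2 * (1:4))
  expect_error(weighted_ls(x_bad, rnorm(4), rep(1, 4)), "z2")
})

test_that("design degrees of freedom is PSUs minus strata", {
  d <- survey_design(rep(1:15, each = 2), rep(1:2, 15), rep(1, 30))
  expect_equal(design_df(d), 15)
  d2 <- survey_design(rep(1:2, each = 2), rep(1:2, 2), rep(1, 4))
  expect_equal(design_df(d2), 2)
  d0 <- survey_design(1:2, c(1, 1), rep(1, 2))
  expect_error(design_df(d0), "at least 1")
})

test_that("design constructor validates and nests PSUs in strata", {
  expect_error(survey_design(1:3, 1:3, c(1, -1, 1)), "positive")
  expect_error(survey_design(1:2, 1:3, rep(1, 3)), "equal length")
  # PSU label reused across strata denotes distinct PSUs
  d <- survey_design(c(1, 1, 2, 2), c(1, 2, 1, 2), rep(1, 4))
  expect_equal(design_df(d), 2)
})

test_that("Taylor covariance: zero between-PSU variability, scale invariance", {
  # two strata, two PSUs each, PSU score totals identical within strata
  d <- data.frame(stratum = rep(1:2, each = 4),
                  psu = rep(rep(1:2, each = 2), 2),
                  w = 1,
                  x = rep(c(0, 1), 4))
  d$y <- rep(c(0.2, 0.9), 4)  # identical records per PSU -> equal totals
  x <- cbind(1, d$x)
  des <- survey_design(d$stratum, d$psu, d$w)
  b <- weighted_ls(x, d$y, d$w)
  v <- taylor_covariance(x, d$y, b, des)
  expect_equal(max(abs(v)), 0, tolerance = 1e-14)

  # rescaling all weights leaves beta and covariance unchanged
  toy <- toy_survey_data()
  xt <- cbind(1, toy$x)
  des1 <- survey_design(toy$stratum, toy$psu, toy$weight)
  des7 <- survey_design(toy$stratum, toy$psu, toy$weight * 7)
  b1 <- weighted_ls(xt, toy$y, des1$weights)
  b7 <- weighted_ls(xt, toy$y, des7$weights)
  expect_equal(b1, b7, tolerance = 1e-10)
  expect_equal(taylor_covariance(xt, toy$y, b1, des1),
               taylor_covariance(xt, toy$y, b7, des7), tolerance = 1e-10)
})

test_that("Taylor covariance agrees with the delete-one-PSU jackknife", {
  toy <- toy_survey_data()
  x <- cbind(1, toy$x)
  des <- survey_design(toy$stratum, toy$psu, toy$weight)
  b <- weighted_ls(x, toy$y, toy$weight)
  v_lin <- taylor_covariance(x, toy$y, b, des)
  v_jk <- jackknife_vcov(x, toy$y, toy)
  expect_equal(diag(v_lin), diag(v_jk), tolerance = 0.15)
  expect_lt(max(abs(v_lin - v_jk)) / max(abs(v_jk)), 0.15)
})

test_that("degenerate design reduces to OLS with robust standard errors", {
  skip_if_not_installed("sandwich")
  set.seed(21)
  n <- 400
  d <- data.frame(x = rnorm(n))
  d$y <- 1 + 0.6 * d$x + rnorm(n, 0, 1 + 0.5 * abs(d$x)) # heteroskedastic
  des <- survey_design(rep(1, n), seq_len(n), rep(1, n))
  fit <- fit_survey_model(y ~ x, d, des)
  ols <- lm(y ~ x, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  se_rob <- sqrt(diag(sandwich::vcovHC(ols, type = "HC1")))
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(se_rob),
               tolerance = 0.10)
})

test_that("fit_survey_model assembles t-based inference on design df", {
  toy <- toy_survey_data()
  des <- survey_design(toy$stratum, toy$psu, toy$weight)
  fit <- fit_survey_model(y ~ x, toy, des, level = 0.95)
  expect_equal(fit$df, 3)
  expect_equal(fit$n, 12)
  tab <- fit$table
  expect_true(all(tab$ci_low < tab$estimate & tab$estimate < tab$ci_high))
  tcrit <- qt(0.975, 3)
  expect_equal(tab$ci_high - tab$estimate, tcrit * tab$se,
               tolerance = 1e-12)
  expect_equal(tab$p, 2 * pt(-abs(tab$estimate / tab$se), 3),
               tolerance = 1e-12)
  # confint() honours a different level
  ci90 <- confint(fit, level = 0.90)
  expect_true(all(ci90[, 1] > tab$ci_low & ci90[, 2] < tab$ci_high))
  # missing values must be excluded beforehand
  toy_na <- toy; toy_na$y[1] <- NA
  expect_error(fit_survey_model(y ~ x, toy_na, des))
})

test_that("singleton-PSU strata follow the configured rule", {
  toy <- toy_survey_data()
  keep <- !(toy$stratum == 2 & toy$psu == 2)
  sub <- toy[keep, ]
  des <- survey_design(sub$stratum, sub$psu, sub$weight)
  expect_warning(fit_survey_model(y ~ x, sub, des, singleton = "centre"),
                 "singleton")
  expect_error(fit_survey_model(y ~ x, sub, des, singleton = "fail"),
               "single PSU")
})

test_that("Wald test: q = 1 equals squared-t, joint test and errors", {
  toy <- toy_survey_data()
  des <- survey_design(toy$stratum, toy$psu, toy$weight)
  fit <- fit_survey_model(y ~ x, toy, des)
  wt <- wald_test(fit, "x")
  # for one term the F test is exactly the squared-t test
  expect_equal(wt$p, fit$table$p[fit$table$term == "x"],
               tolerance = 1e-10)
  expect_equal(wt$statistic,
               (fit$table$estimate[2] / fit$table$se[2])^2,
               tolerance = 1e-10)

  # coefficients exactly zero give W = 0, p = 1
  fake <- structure(list(coefficients = c(a = 0, b = 0),
                         vcov = diag(2), df = 10), class = "svy_fit")
  wt0 <- wald_test(fake, c("a", "b"))
  expect_equal(wt0$statistic, 0)
  expect_equal(wt0$p, 1)

  expect_error(wald_test(fit, "nope"), "unknown")
  sing <- structure(list(coefficients = c(a = 1, b = 1),
                         vcov = matrix(1, 2, 2), df = 10),
                    class = "svy_fit")
  expect_error(wald_test(sing, c("a", "b")), "singular")
})

test_that("point estimates and covariance ignore the weight scale in a fit", {
  g <- generate_cohort(generator_config(n = 400, seed = 9))
  d <- score_dii(score_phenoage(recode_covariates(g$records)))
  des1 <- survey_design(d$stratum, d$psu, d$weight)
  des2 <- survey_design(d$stratum, d$psu, d$weight * 1e3)
  f1 <- fit_survey_model(phenoage ~ diet_class + chron_age, d, des1)
  f2 <- fit_survey_model(phenoage ~ diet_class + chron_age, d, des2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(vcov(f1), vcov(f2), tolerance = 1e-10)
})
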