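test_that("linear predictor matches closed-form evaluation and is linear", {
  p <- fixture_panel()
  expect_equal(compute_xb(p), FIX_XB, tolerance = 1e-9)

  # only the intercept survives when every marker is 0 and crp = 1
  p0 <- data.frame(albumin = 0, creatinine = 0, glucose = 0, crp = 1,
                   lymphocyte_pct = 0, mcv = 0, rdw = 0, alp = 0,
                   wbc = 0, chron_age = 0)
  expect_equal(compute_xb(p0), -19.907)

  # unit changes move xb by exactly the printed coefficient
  p_rdw <- p; p_rdw$rdw <- p$rdw + 1
  expect_equal(compute_xb(p_rdw) - compute_xb(p), 0.3306)
  p_age <- p; p_age$chron_age <- p$chron_age + 10
  expect_equal(compute_xb(p_age) - compute_xb(p), 0.804)

  # doubling a marker's deviation from reference doubles its contribution
  base <- compute_xb(p)
  for (m in setdiff(biomarker_names(), "crp")) {
    p1 <- p; p1[[m]] <- p[[m]] + 2
    p2 <- p; p2[[m]] <- p[[m]] + 4
    expect_equal(compute_xb(p2) - base, 2 * (compute_xb(p1) - base),
                 tolerance = 1e-12)
  }
})

test_that("panel validation rejects bad inputs by name", {
  p <- fixture_panel()
  p_bad <- p; p_bad$glucose <- NA_real_
  expect_error(compute_xb(p_bad), "glucose")
  expect_error(compute_xb(p[-1]), "albumin")
  p_lym <- p; p_lym$lymphocyte_pct <- 120
  expect_error(compute_xb(p_lym), "lymphocyte")
  p_neg <- p; p_neg$chron_age <- -3
  expect_error(compute_xb(p_neg), "chron_age")
})

test_that("CRP flooring keeps the log defined and is configurable", {
  p <- fixture_panel()
  p$crp <- 0
  expect_silent(x1 <- compute_xb(p, crp_floor = 0.01))
  expect_true(is.finite(x1))
  x2 <- compute_xb(p, crp_floor = 0.1)
  expect_equal(x2 - x1, 0.0954 * log(10), tolerance = 1e-12)
})

test_that("mortality score is a proper Gompertz CDF value", {
  cons <- phenoage_constants()
  # exponent collapses to -1 at xb = ln(gamma / scale)
  expect_equal(compute_mortality_score(log(cons$gamma / cons$gompertz_scale)),
               1 - exp(-1), tolerance = 1e-12)
  expect_equal(compute_mortality_score(FIX_XB), FIX_M, tolerance = 1e-9)
  # strictly in (0,1), increasing, overflow-guarded
  xs <- c(-700, -50, -10, 0, 10, 50, 700)
  ms <- compute_mortality_score(xs)
  expect_true(all(ms > 0 & ms < 1))
  expect_true(all(diff(ms) >= 0))
  expect_lt(compute_mortality_score(1000), 1)
  expect_error(compute_mortality_score(NA_real_), "finite")
})

test_that("years-scale transform matches closed form and guards its domain", {
  expect_equal(compute_phenoage(1 - exp(-1)),
               141.50 + log(0.00553) / 0.09165, tolerance = 1e-9)
  expect_equal(compute_phenoage(FIX_M), FIX_PHENOAGE, tolerance = 1e-6)
  expect_error(compute_phenoage(0), "strictly")
  expect_error(compute_phenoage(1), "strictly")
  expect_error(compute_phenoage(-0.1), "strictly")
})

test_that("full chain scores the fixture panel and is monotone per sign", {
  p <- fixture_panel()
  expect_equal(phenoage_from_panel(p), FIX_PHENOAGE, tolerance = 1e-6)
  # pure function: identical across calls
  expect_identical(phenoage_from_panel(p), phenoage_from_panel(p))
  # higher albumin (negative coefficient) strictly lowers PhenoAge
  p_alb <- p; p_alb$albumin <- p$albumin + 5
  expect_lt(phenoage_from_panel(p_alb), phenoage_from_panel(p))

  # the sign of d PhenoAge / d marker equals the printed coefficient sign
  cons <- phenoage_constants()
  signs <- sign(cons$coefs)
  names(signs)[names(signs) == "log_crp"] <- "crp"
  panels <- random_panels(100)
  base <- phenoage_from_panel(panels)
  for (m in c(biomarker_names(), "chron_age")) {
    bumped <- panels
    bumped[[m]] <- bumped[[m]] * 1.01 + 0.01
    expect_true(all(sign(phenoage_from_panel(bumped) - base) ==
                      signs[[m]]),
                label = paste("monotone in", m))
  }
})

test_that("analytic inverse round-trips to machine precision", {
  cons <- phenoage_constants()
  for (xb in c(-12, -9, -6, -3)) {
    p <- compute_phenoage(compute_mortality_score(xb))
    expect_equal(invert_phenoage(p), xb, tolerance = 1e-9)
  }
  grid <- seq(-10, 90, by = 2.5)
  back <- compute_phenoage(compute_mortality_score(invert_phenoage(grid)))
  expect_equal(back, grid, tolerance = 1e-9)
  expect_equal(invert_phenoage(141.50),
               log(0.0076927 / (1.51714 * 0.00553)), tolerance = 1e-9)
  expect_error(invert_phenoage(-1e6), "invertible range")
  expect_error(invert_phenoage(Inf), "finite")
})

test_that("the variant years-scale denominator is switchable", {
  p <- fixture_panel()
  a <- phenoage_from_panel(p, phenoage_constants(0.09165))
  b <- phenoage_from_panel(p, phenoage_constants(0.090165))
  expect_false(isTRUE(all.equal(a, b)))
  # both chains still round-trip through their own inverse
  cb <- phenoage_constants(0.090165)
  expect_equal(compute_phenoage(compute_mortality_score(
    invert_phenoage(50, cb), cb), cb), 50, tolerance = 1e-9)
})

test_that("batch scoring appends phenoage and flags incomplete rows", {
  d <- rbind(fixture_panel(), fixture_panel())
  d$chron_age[2] <- 60
  d$albumin[2] <- NA
  out <- score_phenoage(d)
  expect_equal(out$phenoage[1], FIX_PHENOAGE, tolerance = 1e-6)
  expect_true(is.na(out$phenoage[2]))
  expect_equal(out$phenoage_accel[1], FIX_PHENOAGE - 40, tolerance = 1e-6)
  expect_error(score_phenoage(d[-1]), "albumin")
})
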