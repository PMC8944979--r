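test_that("with no between-subject variance the fit reduces to OLS", {
  d <- simulate_cohort(cohort_spec(seed = 3, tau = 0, sigma = 150))
  f <- fit_random_intercept(d, covariates = "gonial_deg")
  ols <- stats::lm(volume_mm3 ~ gonial_deg, data = d)
  expect_equal(slope_of(f, "gonial_deg")$estimate,
               unname(stats::coef(ols)[2]), tolerance = 1e-6)
})

test_that("duplicating each subject's single row leaves the slope at OLS", {
  set.seed(21)
  n <- 20
  x <- rnorm(n, 120, 6)
  base <- data.frame(
    subject_id = sprintf("Q%02d", 1:n), side = "R",
    volume_mm3 = 2700 - 12 * x + rnorm(n, 0, 150),
    gonial_deg = x
  )
  doubled <- rbind(base, transform(base, side = "L"))
  f <- fit_random_intercept(doubled, covariates = "gonial_deg")
  ols <- stats::lm(volume_mm3 ~ gonial_deg, data = base)
  expect_equal(slope_of(f, "gonial_deg")$estimate,
               unname(stats::coef(ols)[2]), tolerance = 1e-6)
  # duplication is pure between-subject structure: residual variance ~ 0
  expect_lt(f$sigma2, 1e-4 * f$tau2)
})

test_that("REML estimates agree with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  d <- simulate_cohort(cohort_spec(seed = 7))
  f <- fit_random_intercept(d, covariates = c("gonial_deg", "sex",
                                              "age_years"))
  lf <- lme4::lmer(volume_mm3 ~ gonial_deg + sex + age_years +
                     (1 | subject_id), data = d, REML = TRUE)
  expect_equal(f$coefficients$estimate, unname(lme4::fixef(lf)),
               tolerance = 1e-6)
  expect_equal(f$coefficients$se,
               unname(sqrt(diag(as.matrix(stats::vcov(lf))))),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(c(f$tau2, f$sigma2), vc$vcov, tolerance = 1e-4)
})

test_that("slopes are exactly equivariant under covariate scaling", {
  d <- simulate_cohort(cohort_spec(seed = 13))
  f1 <- fit_random_intercept(d, covariates = "divergence_deg")
  d2 <- transform(d, divergence_deg = divergence_deg * 4)
  f2 <- fit_random_intercept(d2, covariates = "divergence_deg")
  expect_equal(slope_of(f2, "divergence_deg")$estimate * 4,
               slope_of(f1, "divergence_deg")$estimate, tolerance = 1e-9)
})

test_that("degenerate designs fail with informative errors", {
  d <- simulate_cohort(cohort_spec(seed = 2))
  d$dup <- d$gonial_deg
  expect_error(fit_random_intercept(d, covariates = c("gonial_deg", "dup")),
               "collinear.*dup")
  two <- d[d$subject_id %in% c("S001", "S002"), ]
  expect_error(fit_random_intercept(two, covariates = "gonial_deg"),
               "at least 3 subjects")
  expect_error(validate_cohort(data.frame()), "lacks column")
  bad <- d; bad$side[2] <- "R"
  expect_error(validate_cohort(bad), "duplicated side")
  trip <- rbind(d, d[1, ])
  expect_error(validate_cohort(trip), "more than two")
})

test_that("Wald interval always contains the estimate and tau2 is non-negative", {
  for (s in c(5, 17, 29)) {
    d <- simulate_cohort(cohort_spec(seed = s))
    f <- fit_random_intercept(d, covariates = "anb_deg")
    expect_gte(f$tau2, 0)
    expect_gte(f$sigma2, 0)
    with(f$coefficients, {
      expect_true(all(ci_lo <= estimate & estimate <= ci_hi))
    })
  }
})
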