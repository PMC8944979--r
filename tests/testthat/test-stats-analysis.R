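test_that("group summaries compute two-point arithmetic and empty levels", {
  d <- tiny_cohort(c(600, 800, 700, 900, 500, 750))
  # all subjects sit at the clinical norms: single central level per axis
  sm <- group_summaries(d)
  normo <- sm[sm$variable == "divergence_class" & sm$level == "normo", ]
  expect_equal(normo$n_condyles, 6)
  hypo <- sm[sm$variable == "divergence_class" & sm$level == "hypo", ]
  expect_equal(hypo$n_condyles, 0)
  expect_true(is.na(hypo$mean))
  # a two-condyle level
  d2 <- tiny_cohort(c(600, 800, 700, 900, 500, 750))
  d2$divergence_deg <- c(39, 39, 41, 41, 43, 43)
  sm2 <- group_summaries(d2)
  h <- sm2[sm2$variable == "divergence_class" & sm2$level == "hypo", ]
  expect_equal(h$mean, 700)
  expect_equal(h$median, 700)
  expect_equal(h$sd, sqrt(sum((c(600, 800) - 700)^2)), tolerance = 1e-9)
  expect_equal(h$min, 600)
  expect_equal(h$max, 800)
})

test_that("simulated group means recover the generator's group structure", {
  # large single cohort: sample group means within a few SEs of expectation
  d <- simulate_cohort(cohort_spec(n_female = 1960, n_male = 960, seed = 77))
  sm <- group_summaries(d)
  dv <- sm[sm$variable == "divergence_class", ]
  means <- stats::setNames(dv$mean, dv$level)
  # generator encodes the hypo > normo > hyper gradient (~60 mm^3 per step)
  expect_gt(means["hypo"] - means["normo"], 25)
  expect_gt(means["normo"] - means["hyper"], 25)
  gr <- sm[sm$variable == "growth_class", ]
  gmeans <- stats::setNames(gr$mean, gr$level)
  expect_gt(gmeans["horizontal"] - gmeans["normal"], 90)
  expect_gt(gmeans["normal"] - gmeans["post_rotation"], 90)
})

test_that("analyze_study produces the crude/adjusted/stratified battery", {
  d <- simulate_cohort(cohort_spec(seed = 31))
  rep <- analyze_study(d)
  expect_s3_class(rep, "study_report")
  expect_named(rep$continuous, c("anb_deg", "divergence_deg", "gonial_deg"))
  for (v in names(rep$continuous)) {
    fits <- rep$continuous[[v]]
    expect_s3_class(fits$crude, "ri_fit")
    expect_s3_class(fits$adjusted, "ri_fit")
    expect_named(fits$by_sex, c("F", "M"))
    expect_s3_class(fits$by_sex$F, "ri_fit")
    # adjusted fit includes the sex and age terms
    expect_true(all(c(v, "sexM", "age_years") %in%
                      fits$adjusted$coefficients$term))
  }
  # categorical fits use the clinical reference groups
  cat_div <- rep$categorical$divergence_class$crude
  expect_true(all(c("divergence_classhypo", "divergence_classhyper") %in%
                    cat_div$coefficients$term))
  tab <- report_table(rep)
  expect_true(all(c("variable", "analysis", "estimate", "p_value") %in%
                    names(tab)))
  expect_gt(nrow(tab), 10)
})

test_that("tiny strata are reported unavailable, not fatal", {
  d <- simulate_cohort(cohort_spec(n_female = 10, n_male = 2, seed = 4))
  rep <- analyze_study(d)
  expect_s3_class(rep$continuous$gonial_deg$by_sex$M, "ri_unavailable")
  expect_s3_class(rep$continuous$gonial_deg$by_sex$F, "ri_fit")
  expect_error(analyze_study(data.frame()), "lacks column|empty")
})

test_that("stratified fits recover sex-specific slopes from mixed cohorts", {
  # female gonial slope -10, male -1 (fit adjusted by age within sex)
  est <- sapply(1:30, function(s) {
    dF <- simulate_cohort(cohort_spec(
      n_female = 49, n_male = 0, seed = 6000 + s,
      slopes = c(anb_deg = 0, divergence_deg = 0, gonial_deg = -10)))
    dM <- simulate_cohort(cohort_spec(
      n_female = 0, n_male = 24, seed = 7000 + s,
      slopes = c(anb_deg = 0, divergence_deg = 0, gonial_deg = -1)))
    dM$subject_id <- sub("S", "T", dM$subject_id)
    rep <- analyze_study(rbind(dF, dM))
    c(F = slope_of(rep$continuous$gonial_deg$by_sex$F,
                   "gonial_deg")$estimate,
      M = slope_of(rep$continuous$gonial_deg$by_sex$M,
                   "gonial_deg")$estimate)
  })
  expect_lt(abs(mean(est["F", ]) - (-10)), 3)
  expect_lt(abs(mean(est["M", ]) - (-1)), 3)
})
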