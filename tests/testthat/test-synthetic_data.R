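test_that("generation is deterministic given the seed", {
  c1 <- small_cohort(n = 60, seed = 123)
  c2 <- small_cohort(n = 60, seed = 123)
  expect_identical(c1$recalls, c2$recalls)
  expect_identical(c1$biomarkers, c2$biomarkers)
  expect_identical(c1$design$rep_weights, c2$design$rep_weights)
  c3 <- small_cohort(n = 60, seed = 124)
  expect_false(identical(c1$biomarkers$egfr, c3$biomarkers$egfr))
})

test_that("generated values respect physiological and design constraints", {
  co <- small_cohort(n = 150, seed = 77)
  b <- co$biomarkers
  expect_true(all(b$egfr > 0))
  expect_true(all(b$acr >= 0))
  expect_true(all(b$hba1c >= 4 & b$hba1c <= 15))
  bp <- c(b$sys1, b$sys2, b$sys3[!is.na(b$sys3)])
  expect_true(all(bp >= 70 & bp <= 250))
  dp <- c(b$dia1, b$dia2, b$dia3[!is.na(b$dia3)])
  expect_true(all(dp >= 40 & dp <= 150))
  expect_true(all(co$design$weight > 0))
  expect_true(all(co$design$rep_weights >= 0))
  # third reading exists exactly when the first two differ by > 10 mmHg
  third <- abs(b$sys1 - b$sys2) > 10 | abs(b$dia1 - b$dia2) > 10
  expect_equal(!is.na(b$sys3), third)
  # replicate weights are delete-a-group: each column zeroes one group
  expect_true(all(colSums(co$design$rep_weights == 0) >= 1))
  expect_true(all(co$demographics$age >= 18))
})

test_that("recall records decompose back to the generated intake matrices", {
  co <- small_cohort(n = 50, seed = 31)
  ci <- cohort_intakes(co$recalls, co$composition)
  expect_equal(ci$day1, co$intakes$day1, tolerance = 1e-9)
  expect_equal(ci$mean, co$intakes$mean, tolerance = 1e-9)
  # mixed-dish cake records are present and decomposition still conserves mass
  expect_true("20000001" %in% co$recalls$food_code)
  expect_equal(sum(ci$day1) + sum(ci$day2), sum(co$recalls$grams),
               tolerance = 1e-8)
})

test_that("missingness injection is MAR with binomial counts and a seeded mask", {
  co <- small_cohort(n = 200, seed = 55)
  expect_identical(inject_missingness(co, 0), co)
  m1 <- inject_missingness(co, 0.1, seed = 9, fields = "egfr")
  m2 <- inject_missingness(co, 0.1, seed = 9, fields = "egfr")
  expect_identical(m1$biomarkers$egfr, m2$biomarkers$egfr)
  k <- sum(is.na(m1$biomarkers$egfr))
  expect_gt(k, qbinom(0.0005, 200, 0.1))   # ~20 expected
  expect_lt(k, qbinom(0.9995, 200, 0.1))
  expect_error(inject_missingness(co, 1), "rate")
  expect_error(inject_missingness(co, 0.1, fields = "no_such"), "unknown field")
})

test_that("fixture write/read round-trips and regenerates byte-identically", {
  co <- small_cohort(n = 50, seed = 404)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  write_fixture(co, d1)
  write_fixture(generate_cohort(generator_config(n = 50, seed = 404)), d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  back <- read_fixture(d1)
  expect_equal(back$demographics, co$demographics)
  expect_equal(back$biomarkers, co$biomarkers, tolerance = 1e-12)
  expect_equal(back$design$weight, co$design$weight, tolerance = 1e-12)
  expect_equal(back$design$rep_weights, co$design$rep_weights,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(nrow(back$recalls), nrow(co$recalls))
  # the read-back fixture feeds the pipeline
  ci <- cohort_intakes(back$recalls, back$composition)
  expect_equal(ci$mean, co$intakes$mean, tolerance = 1e-6)
})

test_that("a null injected effect yields a null fitted uPDI association", {
  set.seed(1)
  ests <- replicate(30, {
    seed <- sample.int(1e6, 1)
    co <- generate_cohort(generator_config(n = 500, seed = seed,
                                           updi_ckd_log_or = 0))
    tab <- build_analysis_table(co)
    fit <- fit_survey_glm(
      moderate_severe ~ updi + age + sex + energy_kj + education +
        physical_activity + smoking + diabetes + hypertension + bmi +
        alcohol_g,
      tab$data, tab$design, family = "logistic")
    fit_term(fit, "updi")$estimate
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 3 * mc_se + 1e-3)
})

test_that("an infeasible prevalence target raises a calibration error", {
  expect_error(generate_cohort(generator_config(
    n = 60, seed = 1, ckd_prevalence_target = 1e-20,
    moderate_severe_fraction = 0.412)), "calibration failure")
})
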