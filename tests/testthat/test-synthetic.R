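test_that("quantile anchors invert linearly", {
  sleep <- cohort_calibration()$sleep_24h
  expect_equal(quantile_sample(sleep, 0.5), 690.5)
  expect_equal(quantile_sample(sleep, 0), 603)
  expect_equal(quantile_sample(sleep, 1), 1100)
  expect_equal(quantile_sample(data.frame(p = c(0, 1), value = c(0, 100)), 0.25), 25)
  expect_error(quantile_sample(data.frame(p = c(0, 0.5), value = c(2, 1)), 0.5),
               "non-decreasing")
  expect_error(cohort_calibration(medication_uptake = 1.3), "\\[0, 1\\]")
})

test_that("the generator is deterministic given seed and config", {
  cfg <- generator_config(10, seed = 99)
  r1 <- sample_cohort(config = cfg)
  r2 <- sample_cohort(config = cfg)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".yaml"); f2 <- tempfile(fileext = ".yaml")
  write_patients(r1, f1); write_patients(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed changes the cohort
  expect_false(identical(r1, sample_cohort(config = generator_config(10, seed = 100))))
})

test_that("generated cohorts are structurally valid study cohorts", {
  recs <- sample_cohort(config = generator_config(43, seed = 2))
  expect_length(recs, 43)
  reg <- default_registry()
  for (rec in recs) {
    expect_gte(rec$interview_year - rec$onset_year, 1)
    m <- build_patient_model(rec, reg) # runs full validation
    expect_s3_class(m, "patient_model")
  }
})

test_that("a zero-prevalence comorbidity never appears", {
  prev <- cohort_calibration()$comorbidity_prevalence
  prev[["depression_diagnosis"]] <- 0
  cal <- cohort_calibration(comorbidity_prevalence = prev)
  recs <- sample_cohort(cal, generator_config(60, seed = 4))
  has_dep <- vapply(recs, function(r)
    !is.null(r$parameters$depression_diagnosis), logical(1))
  expect_false(any(has_dep))
})

test_that("moderate cohorts already recover the calibrated marginals", {
  recs <- sample_cohort(config = generator_config(3000, seed = 8))
  s <- cohort_summary(recs)
  expect_lt(abs(s$median_sleep_24h - 690.5) / 690.5, 0.02)
  expect_lt(abs(s$pct_sleep_gt_660 - 78.6), 2.5)
  expect_lt(abs(s$pct_ess_gt_10 - 85), 2.5)
  expect_lt(abs(s$pct_mslt_lt_8 - 73.8), 2.5)
  expect_lt(abs(100 * s$prevalence[["depression_diagnosis"]] - 27.3), 3)
})

test_that("self-consistent reports reproduce the simulated course verbatim", {
  cfg <- generator_config(6, seed = 12, report_mode = "self_consistent")
  recs <- sample_cohort(config = cfg)
  models <- lapply(recs, build_patient_model)
  results <- lapply(models, simulate_patient)
  recs <- attach_reports(recs, results, cfg)
  for (i in seq_along(recs))
    expect_identical(recs[[i]]$reported_course$values, results[[i]]$experience)
})

test_that("noisy reports carry a template choice and degrade the fit", {
  cfg <- generator_config(15, seed = 21, report_mode = "template_noisy",
                          report_noise = 0.5)
  recs <- sample_cohort(config = cfg)
  models <- lapply(recs, build_patient_model)
  results <- lapply(models, simulate_patient)
  recs <- attach_reports(recs, results, cfg)
  ids <- vapply(recs, function(r) r$reported_course$template_id, numeric(1))
  expect_true(all(ids %in% 1:9))
  fits <- Map(function(rec, res)
    fit_percentage(res$experience, rec$reported_course$values), recs, results)
  pooled <- cohort_fit(fits)
  expect_lt(pooled, 80)
  expect_gt(pooled, 20)
})
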