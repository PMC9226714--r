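test_that("aggregate schedules combine members by mean or clamped sum", {
  yrs <- 0:5
  a <- target_schedule("a", yrs, rep(40, 6))
  b <- target_schedule("b", yrs, rep(60, 6))
  expect_equal(aggregate_schedule(list(a, b), "mean")$targets, rep(50, 6))
  expect_equal(aggregate_schedule(list(a), "mean")$targets, a$targets)

  c1 <- target_schedule("c", yrs, rep(80, 6))
  expect_equal(aggregate_schedule(list(c1, c1), "sum")$targets, rep(100, 6))

  expect_error(aggregate_schedule(list(), "mean"), "empty member")
  mis <- target_schedule("d", 1:6, rep(1, 6))
  expect_error(aggregate_schedule(list(a, mis)), "mismatched year axes")
})

test_that("the shipped registry partitions 71 parameters with the published counts", {
  reg <- default_registry()
  expect_equal(nrow(reg), 71)
  expect_equal(anyDuplicated(reg$name), 0L)
  expect_setequal(unique(reg$aggregate), aggregate_names())
  counts <- table(reg$aggregate)
  expect_equal(unname(counts[["Somatic pathologies"]]), 24L)
  expect_equal(unname(counts[["Naps"]]), 6L)
})

test_that("registry validation rejects broken partitions", {
  reg <- default_registry()
  tmp <- tempfile(fileext = ".csv")

  bad <- as.data.frame(reg)
  bad$aggregate[1] <- "Weather"
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_registry(tmp), "unknown aggregate 'Weather'")

  dup <- as.data.frame(reg)
  dup$name[2] <- dup$name[1]
  write.csv(dup, tmp, row.names = FALSE)
  expect_error(read_registry(tmp), "duplicated parameter name")

  gone <- as.data.frame(reg)[reg$aggregate != "Naps", ]
  write.csv(gone, tmp, row.names = FALSE)
  expect_error(read_registry(tmp), "no member parameters: Naps")
})

test_that("patient models are assembled with all twelve aggregates", {
  # a record with no phenomena yields twelve all-zero schedules
  m0 <- build_patient_model(make_record(onset = 2010, interview = 2020))
  expect_setequal(names(m0$aggregate_schedules), aggregate_names())
  for (a in aggregate_names()) {
    sch <- m0$aggregate_schedules[[a]]
    expect_equal(sch$years, 2010:2020)
    expect_equal(sch$targets, rep(0, 11))
  }
  expect_equal(length(m0$parameter_schedules), 71)

  # depression only: exactly one non-zero aggregate
  rec <- make_record(parameters = list(
    bdi_severity = list(first_occurrence_year = 2012, max_value = 30)))
  m1 <- build_patient_model(rec)
  nz <- vapply(m1$aggregate_schedules, function(s) any(s$targets != 0), logical(1))
  expect_equal(names(nz)[nz], "Depression")

  # unknown parameter names are rejected with the field identified
  bad <- make_record(parameters = list(teleportation = list(static = 1)))
  expect_error(build_patient_model(bad), "unknown name.*teleportation")
})

test_that("synthetic records round-trip structurally through model building", {
  recs <- sample_cohort(config = generator_config(5, seed = 5))
  for (rec in recs) {
    m <- build_patient_model(rec)
    expect_equal(length(m$parameter_schedules), 71)
    yrs <- rec$onset_year:rec$interview_year
    for (s in m$aggregate_schedules) expect_equal(s$years, yrs)
    # every recorded phenomenon produced a non-zero parameter schedule
    for (nm in names(rec$parameters)) {
      entry <- rec$parameters[[nm]]
      if (!is.null(entry$static) && entry$static == 0) next
      if (!is.null(entry$max_value) && entry$max_value == 0) next
      expect_true(any(m$parameter_schedules[[nm]]$targets != 0), label = nm)
    }
  }
})

test_that("scenario windows select patients and years without altering values", {
  m_long <- make_min_model(onset = 2000, interview = 2010,
                           targets = list("Sleepiness" = -60), id = "LONG")
  m_short <- make_min_model(onset = 2019, interview = 2020, id = "SHORT")
  models <- list(m_long, m_short)
  results <- lapply(models, simulate_patient)

  base <- apply_scenario(results, models, "baseline")
  expect_length(base, 2)
  expect_identical(base[[1]], results[[1]])

  last5 <- apply_scenario(results, models, "last5")
  expect_length(last5, 1) # the one-year patient is excluded
  expect_equal(last5[[1]]$years, 2006:2010)
  keep <- results[[1]]$years >= 2006
  expect_identical(last5[[1]]$aggregates, results[[1]]$aggregates[keep, ])
  expect_identical(last5[[1]]$experience, results[[1]]$experience[keep])

  # unmedicated cohort: the medicated scenario selects nobody
  expect_error(apply_scenario(results, models, "medicated_only"),
               "medicated_only.*no patients")

  m_med <- m_long
  m_med$patient_id <- "MED"
  m_med$medication_flags$modafinil <- list(list(start_year = 2008, stop_year = 2010))
  models2 <- list(m_long, m_med)
  results2 <- lapply(models2, simulate_patient)
  med <- apply_scenario(results2, models2, "medicated_only")
  expect_length(med, 1)
  expect_equal(med[[1]]$patient_id, "MED")
})
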