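test_that("normalization maps instrument scales onto [0, 100]", {
  ess <- raw_parameter("ess_score", "continuous", 0, 24, "always_negative")
  expect_equal(normalize_value(24, ess), 100)
  expect_equal(normalize_value(12, ess), 50)
  expect_equal(normalize_value(0, ess), 0)

  # ordinal categories land evenly spaced: 100 * (k - 1) / (K - 1)
  for (K in c(3, 5, 7)) {
    ord <- raw_parameter("ord", "ordinal", 1, K, "always_negative")
    for (k in 1:K)
      expect_equal(normalize_value(k, ord), 100 * (k - 1) / (K - 1))
  }

  bin <- raw_parameter("bin", "binary", 0, 1, "always_negative")
  expect_equal(normalize_value(0, bin), 0)
  expect_equal(normalize_value(1, bin), 100)
})

test_that("normalization is monotone and clamps out-of-scale values with a warning", {
  par <- raw_parameter("x", "continuous", 0, 10, "always_negative")
  vals <- sort(runif(25, 0, 10))
  norm <- vapply(vals, normalize_value, numeric(1), parameter = par)
  expect_true(all(diff(norm) >= 0))
  expect_warning(hi <- normalize_value(12, par), "clamped")
  expect_equal(hi, 100)

  noscale <- raw_parameter("y", "continuous", polarity = "always_negative")
  expect_error(normalize_value(5, noscale), "'y'.*no instrument scale")
  expect_equal(normalize_value(5, noscale, cohort_range = c(0, 10)), 50)
})

test_that("dynamic specs dynamize into the expected step schedules", {
  # phenomenon active in a bounded window takes its normalized extreme value
  dep <- raw_parameter("depression", "continuous", 0, 100, "always_negative",
    dynamic_spec = dynamic_spec(2005, 2010, max_value = 60))
  sch <- build_target_schedule(dep, 2000, 2015)
  expect_equal(sch$targets, c(rep(0, 5), rep(-60, 6), rep(0, 5)))
  expect_equal(sch$increasing - sch$decreasing, sch$targets)

  # static parameter gives a constant schedule
  stat <- raw_parameter("s", "continuous", 0, 100, "always_positive",
                        static_value = 40)
  expect_equal(build_target_schedule(stat, 2000, 2005)$targets, rep(40, 6))

  # change events step the target piecewise-constantly
  par <- raw_parameter("p", "continuous", 0, 100, "always_positive",
    dynamic_spec = dynamic_spec(3, max_value = 80,
      change_events = list(list(year = 3, value = 80), list(year = 6, value = 20))))
  expect_equal(build_target_schedule(par, 0, 8)$targets,
               c(0, 0, 0, 80, 80, 80, 20, 20, 20))
})

test_that("dynamization validates events, polarity and window", {
  par <- raw_parameter("p", "continuous", 0, 100, "always_negative",
    dynamic_spec = dynamic_spec(2005, 2010, max_value = 50,
      change_events = list(list(year = 2012, value = 10))))
  expect_error(build_target_schedule(par, 2000, 2015), "change event outside")

  nap <- raw_parameter("nap", "continuous", 0, 100, "data_dependent",
    dynamic_spec = dynamic_spec(2005, max_value = 50))
  expect_error(build_target_schedule(nap, 2000, 2010), "perception flag")
  nap$dynamic_spec$perceived_positive <- TRUE
  expect_equal(build_target_schedule(nap, 2000, 2010)$targets[6], 50)

  expect_error(dynamic_spec(2010, 2005, max_value = 1), "exceeds")
  expect_error(target_schedule("t", 1:3, c(0, 101, 0)), "within")
})

test_that("linear mode ramps between change events", {
  par <- raw_parameter("p", "continuous", 0, 100, "always_positive",
    dynamic_spec = dynamic_spec(0, max_value = 0,
      change_events = list(list(year = 0, value = 0), list(year = 4, value = 80))))
  sch <- build_target_schedule(par, 0, 6, mode = "linear")
  expect_equal(sch$targets, c(0, 20, 40, 60, 80, 80, 80))
})

test_that("event replay oracle reproduces 100 random dynamic schedules exactly", {
  set.seed(42)
  pick <- function(x) x[sample.int(length(x), 1)]
  for (i in 1:100) {
    onset <- 2000
    horizon <- 2000 + pick(5:30)
    first <- pick(onset:horizon)
    last <- if (runif(1) < 0.5) NULL else pick(first:horizon)
    span_end <- if (is.null(last)) horizon else last
    max_val <- runif(1, 10, 100)
    n_ev <- sample(0:3, 1)
    ev_years <- if (n_ev && span_end > first)
      sort(sample(first:span_end, min(n_ev, span_end - first + 1))) else integer(0)
    events <- lapply(ev_years, function(y)
      list(year = y, value = runif(1, 0, 100)))
    sgn <- sample(c(-1, 1), 1)
    par <- raw_parameter("p", "continuous", 0, 100,
      polarity = if (sgn < 0) "always_negative" else "always_positive",
      dynamic_spec = dynamic_spec(first, last, max_value = max_val,
                                  change_events = events))
    sch <- build_target_schedule(par, onset, horizon)
    ev_norm <- lapply(events, function(e) list(year = e$year, value = e$value))
    expected <- oracle_replay_schedule(first, last, max_val, ev_norm,
                                       sgn, onset, horizon)
    expect_equal(sch$targets, expected)
    expect_true(all(abs(sch$targets) <= 100))
  }
})

test_that("medication schedules decay after discontinuation", {
  med <- raw_parameter("methylphenidate_effect", "continuous", 0, 100,
                       "data_dependent")
  sch <- build_medication_schedule(
    list(list(start_year = 10, stop_year = 12, effect = 40)),
    med, onset_year = 8, horizon_year = 16, persistence = 1)
  expect_equal(sch$targets, c(0, 0, 40, 40, 40, 20, 0, 0, 0))

  expect_equal(build_medication_schedule(list(), med, 0, 5)$targets, rep(0, 6))
  zero_eff <- list(list(start_year = 1, stop_year = 3, effect = 0))
  expect_equal(build_medication_schedule(zero_eff, med, 0, 5)$targets, rep(0, 6))

  overlap <- list(list(start_year = 1, stop_year = 5, effect = 10),
                  list(start_year = 4, stop_year = 8, effect = 10))
  expect_error(build_medication_schedule(overlap, med, 0, 10), "overlapping")

  # negatively perceived medication pushes the target down
  bad <- list(list(start_year = 1, stop_year = 2, effect = 30,
                   perceived_positive = FALSE))
  expect_equal(build_medication_schedule(bad, med, 0, 4)$targets,
               c(0, -30, -30, -15, 0))
})
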