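# Independent oracles and fixture builders shared across the suite.

# Event-by-event replay of a dynamic spec: walks the window one year at a
# time keeping the currently active magnitude, entirely independent of the
# vectorised schedule construction (step mode).
oracle_replay_schedule <- function(first, last, max_norm, events_norm,
                                   sign, onset, horizon) {
  years <- onset:horizon
  g <- numeric(length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    if (y < first || y > (if (is.null(last)) horizon else last)) next
    mag <- max_norm
    for (e in events_norm) if (e$year <= y) mag <- e$value
    g[i] <- sign * mag
  }
  g
}

# Year-by-year replay of the Euler recursion, written as a plain loop over a
# target vector with scalar arithmetic (no step_rate call).
oracle_euler <- function(iv, targets, d, mode) {
  n <- length(targets)
  pv <- numeric(n + 1)
  pv[1] <- iv
  for (t in seq_len(n)) {
    g <- targets[t]
    raw <- (g - pv[t]) / d
    rate <- if (mode == "literal") {
      min(raw, g)
    } else if (g != 0) {
      sign(raw) * min(abs(raw), abs(g))
    } else raw
    pv[t + 1] <- pv[t] + rate
  }
  pv
}

# Exhaustive permutation oracle for the Mann-Whitney test: enumerates every
# assignment of the pooled values to group A, computes the U distribution
# and a symmetric two-sided p. Assumes no ties.
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  list(U = u_obs, p = p)
}

# Minimal hand-built patient model: aggregate schedules default to zero,
# selected aggregates overridden with constant targets.
make_min_model <- function(onset = 2000, interview = 2010,
                           targets = list(), delays = NULL, id = "T1") {
  aggs <- aggregate_names()
  schedules <- lapply(stats::setNames(nm = aggs), function(a)
    zero_schedule(a, onset, interview))
  for (a in names(targets)) {
    yrs <- onset:interview
    schedules[[a]] <- target_schedule(a, yrs, rep(targets[[a]], length(yrs)))
  }
  if (is.null(delays)) delays <- as.list(rep(1, length(aggs)))
  names(delays) <- aggs
  structure(
    list(patient_id = id, onset_year = onset, interview_year = interview,
         parameter_schedules = list(),
         aggregate_schedules = schedules,
         aggregate_delays = delays,
         initial_values = list(), reported_course = NULL,
         medication_flags = list(methylphenidate = list(), modafinil = list())),
    class = "patient_model")
}

# Fabricated simulation result with per-aggregate constant levels.
make_fake_result <- function(id, years, values) {
  aggs <- aggregate_names()
  mat <- matrix(0, nrow = length(years), ncol = length(aggs),
                dimnames = list(NULL, aggs))
  for (a in names(values)) mat[, a] <- values[[a]]
  structure(list(patient_id = id, years = years, aggregates = mat,
                 experience = rowSums(mat)),
            class = "simulation_result")
}

# Minimal valid patient record.
make_record <- function(id = "P1", onset = 2010, interview = 2020,
                        parameters = list(), medications = list(),
                        reported_course = NULL) {
  rec <- list(patient_id = id, onset_year = onset, interview_year = interview,
              age_interview = 40, age_onset = 40 - (interview - onset),
              ess_onset = 15, mslt_latency = 5, sleep_24h = 690,
              parameters = parameters, medications = medications)
  if (!is.null(reported_course)) rec$reported_course <- reported_course
  rec
}

# Pooled derivative-sign fit for a synthetic cohort at a given noise level.
pooled_fit_at <- function(noise, seed, n = 40) {
  cfg <- generator_config(n, seed = seed, report_mode = "template_noisy",
                          report_noise = noise)
  recs <- sample_cohort(config = cfg)
  models <- lapply(recs, build_patient_model)
  results <- lapply(models, simulate_patient)
  recs <- attach_reports(recs, results, cfg)
  fits <- Map(function(rec, res)
    fit_percentage(res$experience, rec$reported_course$values,
                   patient_id = rec$patient_id), recs, results)
  cohort_fit(fits)
}
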