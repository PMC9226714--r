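#' Calibration of the synthetic cohort generator
#'
#' Quantile anchors (piecewise-linear inverse CDFs through the published
#' cohort quantiles and threshold proportions), comorbidity prevalences,
#' medication uptake, and the mixture over the nine reported-course
#' templates. Defaults reproduce the study cohort's marginals: 24-h sleep
#' median 690.5 min with 78.6% above 660 min, ESS above 10 in 85%, MSLT
#' latency below 8 min in 73.8%, and the published comorbidity frequencies
#' (e.g. depression 27.3%).
#'
#' @param sleep_24h,ess_onset,mslt_latency,age_interview,age_onset quantile
#'   anchor tables: data.frames with columns `p` (strictly increasing in
#'   \[0, 1\]) and `value` (non-decreasing, native units)
#' @param comorbidity_prevalence named vector of Bernoulli prevalences keyed
#'   by registry parameter name
#' @param medication_uptake probability of stimulant exposure in the last
#'   five years before interview (33 of 40 in the study)
#' @param pattern_weights mixture weights over template ids 1-9
#' @return object of class `cohort_calibration`
#' @export
cohort_calibration <- function(
    sleep_24h = data.frame(p = c(0, 0.214, 0.5, 1),
                           value = c(603, 660, 690.5, 1100)),
    ess_onset = data.frame(p = c(0, 0.15, 0.5, 1), value = c(6, 10, 15, 23)),
    mslt_latency = data.frame(p = c(0, 0.5, 0.738, 1), value = c(1, 5.2, 8, 15.9)),
    age_interview = data.frame(p = c(0, 0.5, 1), value = c(20, 43, 67)),
    age_onset = data.frame(p = c(0, 0.5, 1), value = c(6, 18, 52)),
    comorbidity_prevalence = default_comorbidity_prevalence(),
    medication_uptake = 33 / 40,
    pattern_weights = rep(1 / 9, 9)) {
  anchors <- list(sleep_24h = sleep_24h, ess_onset = ess_onset,
                  mslt_latency = mslt_latency, age_interview = age_interview,
                  age_onset = age_onset)
  for (nm in names(anchors)) validate_anchors(anchors[[nm]], nm)
  if (any(comorbidity_prevalence < 0 | comorbidity_prevalence > 1))
    abort_ih("comorbidity prevalences must lie in [0, 1]")
  if (medication_uptake < 0 || medication_uptake > 1)
    abort_ih("medication_uptake must lie in [0, 1]")
  if (length(pattern_weights) != 9 || any(pattern_weights < 0))
    abort_ih("pattern_weights must be 9 non-negative weights")
  structure(
    c(anchors,
      list(comorbidity_prevalence = comorbidity_prevalence,
           medication_uptake = medication_uptake,
           pattern_weights = pattern_weights / sum(pattern_weights))),
    class = "cohort_calibration")
}

validate_anchors <- function(anchors, name) {
  if (!all(c("p", "value") %in% names(anchors)))
    abort_ih("anchors '", name, "': need columns p and value")
  if (any(anchors$p < 0 | anchors$p > 1) || is.unsorted(anchors$p, strictly = TRUE))
    abort_ih("anchors '", name, "': probabilities must be strictly increasing in [0, 1]")
  if (is.unsorted(anchors$value, strictly = FALSE))
    abort_ih("anchors '", name, "': values must be non-decreasing")
  invisible(anchors)
}

# published comorbidity frequencies, plus small face-validity prevalences for
# the rarer somatic conditions mentioned only by count
default_comorbidity_prevalence <- function() {
  c(headaches = 0.523, vertebrogenous_pain = 0.477, gastrointestinal = 0.364,
    depression_diagnosis = 0.273, serious_infections = 0.273, obesity = 0.227,
    hypertension = 0.205, cardiovascular = 0.205, autoimmune_non_cns = 0.205,
    other_psychiatric_diagnosis = 0.182, thyreopathy = 0.182,
    respiratory = 0.182, urologic = 0.182, vegetative_dysfunction = 0.159,
    anxiety_disorder = 0.136, inflammatory_cns = 0.114,
    endocrine_disorder = 0.09, epilepsy = 0.07, neuroimmunological = 0.07,
    malignancy = 0.07, cognitive_deficit = 0.023, diabetes = 0.023,
    rheumatoid_arthritis = 0.023, chronic_pain = 0.1, allergy = 0.15,
    dermatologic = 0.05, anemia = 0.05, substance_abuse = 0.07,
    adjustment_disorder = 0.07)
}

#' Generator configuration
#'
#' @param n_patients number of records to generate (>= 1)
#' @param seed integer RNG seed; identical seed and config give identical
#'   records
#' @param report_mode how reported courses are attached by
#'   [attach_reports()]: `"self_consistent"` (the simulated experience
#'   itself) or `"template_noisy"` (nearest of the nine templates with
#'   per-segment corruption)
#' @param report_noise probability of corrupting each segment class in
#'   `template_noisy` mode
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_patients, seed = 1L,
                             report_mode = c("self_consistent", "template_noisy"),
                             report_noise = 0) {
  report_mode <- match.arg(report_mode)
  if (n_patients < 1) abort_ih("n_patients must be >= 1")
  if (report_noise < 0 || report_noise > 1)
    abort_ih("report_noise must lie in [0, 1]")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 report_mode = report_mode, report_noise = report_noise),
            class = "generator_config")
}

#' Sample from a piecewise-linear inverse CDF
#'
#' Linear interpolation of the anchor polyline at the uniform variate u:
#' u = 0 returns the minimum anchor value, the anchored probabilities return
#' their anchored values exactly.
#'
#' @param anchors data.frame with columns `p`, `value`
#' @param u uniform variate(s) in \[0, 1\]
#' @return native-units value(s)
#' @export
quantile_sample <- function(anchors, u) {
  validate_anchors(anchors, "quantile_sample")
  if (any(u < 0 | u > 1)) abort_ih("u must lie in [0, 1]")
  stats::approx(anchors$p, anchors$value, xout = u, method = "linear",
                rule = 2)$y
}

# run fn under a deterministic RNG stream without disturbing the caller's
with_rng <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

# draw a dynamic spec for one present phenomenon
sample_dynamic_entry <- function(registry_row, onset_year, interview_year) {
  duration <- interview_year - onset_year
  first <- onset_year + sample.int(min(3, duration + 1), 1) - 1L
  # most phenomena persist to interview; ~15% resolve earlier
  last <- NULL
  if (stats::runif(1) < 0.15 && first < interview_year - 1)
    last <- first + sample.int(interview_year - 1 - first, 1)
  lo <- registry_row$scale_min
  hi <- registry_row$scale_max
  max_value <- switch(registry_row$kind,
    binary = 1, nominal = 1,
    ordinal = sample(seq(ceiling(lo + (hi - lo) / 2), hi), 1),
    continuous = stats::runif(1, lo + 0.4 * (hi - lo), hi))
  events <- list()
  span_end <- (if (is.null(last)) interview_year else last)
  if (registry_row$kind %in% c("ordinal", "continuous") &&
      stats::runif(1) < 0.4 && span_end - first >= 2) {
    ev_year <- first + sample.int(span_end - first, 1)
    ev_value <- switch(registry_row$kind,
      ordinal = sample(seq(lo, hi), 1),
      continuous = stats::runif(1, lo, hi))
    events <- list(list(year = ev_year, value = round(ev_value, 1), rate = "step"))
  }
  entry <- list(first_occurrence_year = first,
                max_value = if (is.numeric(max_value)) round(max_value, 1) else max_value,
                change_events = events)
  if (!is.null(last)) entry$last_occurrence_year <- last
  if (registry_row$polarity == "data_dependent")
    entry$perceived_positive <- stats::runif(1) < 0.7
  entry
}

#' Generate a synthetic patient cohort
#'
#' Samples one record per patient with the marginal structure of the study
#' cohort: demographics from the calibrated quantile anchors (interview and
#' onset ages resampled until the disease duration is at least one year),
#' comorbidities as independent Bernoulli draws at the calibrated
#' prevalences, core sleep/impairment symptoms present with high probability,
#' stimulant episodes in the last five years at the calibrated uptake, and a
#' reported-course template drawn from the pattern mixture. Marginals are
#' sampled independently; no joint structure is imposed.
#'
#' @param calibration a [cohort_calibration()]
#' @param config a [generator_config()]
#' @param registry an `ih_registry`
#' @return list of patient records (the format consumed by
#'   [build_patient_model()] and written by [write_patients()])
#' @export
sample_cohort <- function(calibration = cohort_calibration(),
                          config = generator_config(43),
                          registry = default_registry()) {
  interview_year <- 2020L
  core_aggregates <- c("Sleep inertia", "Work and social impairment",
                       "Sleepiness", "Fatigue", "Naps", "Nocturnal sleep")
  prev <- calibration$comorbidity_prevalence
  # row-wise list view of the registry (much cheaper than repeated
  # data.frame row subsetting inside the per-patient loop)
  reg_rows <- lapply(seq_len(nrow(registry)), function(j)
    as.list(registry[j, , drop = FALSE]))
  with_rng(config$seed, function() {
    lapply(seq_len(config$n_patients), function(i) {
      repeat {
        age_int <- round(quantile_sample(calibration$age_interview, stats::runif(1)))
        age_on <- round(quantile_sample(calibration$age_onset, stats::runif(1)))
        duration <- age_int - age_on
        if (duration >= 1) break
      }
      onset_year <- interview_year - duration
      sleep_24h <- round(quantile_sample(calibration$sleep_24h, stats::runif(1)), 1)
      ess <- round(quantile_sample(calibration$ess_onset, stats::runif(1)), 1)
      mslt <- round(quantile_sample(calibration$mslt_latency, stats::runif(1)), 1)

      params <- list()
      for (row in reg_rows) {
        if (row$aggregate %in% c("Methylphenidate effect", "Modafinil effect")) next
        present <- if (row$name %in% names(prev)) {
          stats::runif(1) < prev[[row$name]]
        } else if (row$aggregate %in% core_aggregates) {
          stats::runif(1) < 0.8
        } else if (row$aggregate %in% c("Anxiety", "Depression")) {
          # sub-symptoms only plausible alongside the diagnosis draw
          diag <- if (row$aggregate == "Anxiety") "anxiety_disorder" else
            "depression_diagnosis"
          !is.null(params[[diag]]) && stats::runif(1) < 0.7
        } else {
          FALSE
        }
        if (!present) next
        if (row$name == "ess_score") {
          entry <- list(first_occurrence_year = onset_year, max_value = ess,
                        change_events = list())
        } else if (row$name == "sleep_length_24h") {
          entry <- list(static = sleep_24h,
                        perceived_positive = stats::runif(1) < 0.7)
        } else {
          entry <- sample_dynamic_entry(row, onset_year, interview_year)
        }
        params[[row$name]] <- entry
      }

      medications <- list()
      if (stats::runif(1) < calibration$medication_uptake) {
        drugs <- c("methylphenidate", "modafinil")
        pick <- sample(c("methylphenidate", "modafinil", "both"), 1,
                       prob = c(0.45, 0.35, 0.2))
        chosen <- if (pick == "both") drugs else pick
        for (drug in chosen) {
          start <- interview_year - sample.int(min(5, duration), 1)
          medications[[drug]] <- list(list(
            start_year = start, stop_year = interview_year,
            effect = round(stats::runif(1, 20, 60)),
            perceived_positive = stats::runif(1) < 0.9))
        }
      }

      list(patient_id = sprintf("SYN%04d", i),
           onset_year = onset_year, interview_year = interview_year,
           age_interview = age_int, age_onset = age_on,
           ess_onset = ess, mslt_latency = mslt, sleep_24h = sleep_24h,
           parameters = params,
           medications = medications,
           reported_course = list(
             source = "template",
             template_id = sample.int(9, 1, prob = calibration$pattern_weights)))
    })
  })
}

#' Attach reported courses derived from simulation results
#'
#' In `self_consistent` mode each patient's reported course is their own
#' simulated experience (so the pooled fit is 100% by construction — the
#' pipeline's end-to-end smoke test). `template_noisy` mode emulates an
#' imperfect retrospective report: the patient is assumed to recall the
#' direction of change of their experience year by year, so the report is
#' synthesised from the simulated course's segment-class sequence after each
#' class has been corrupted independently with probability `report_noise`
#' (a corrupted class always differs, so the expected pooled fit degrades
#' roughly as 100 x (1 - report_noise)). The nearest of the nine plotted
#' templates is recorded as the patient's template choice.
#'
#' @param records list of patient records
#' @param results aligned list of `simulation_result`
#' @param config a [generator_config()] (supplies mode, noise and seed)
#' @return records with a `reported_course` of source `"series"`
#' @export
attach_reports <- function(records, results, config) {
  if (length(records) != length(results))
    abort_ih("attach_reports: records and results differ in length")
  with_rng(config$seed + 1L, function() {
    Map(function(rec, res) {
      stopifnot(identical(as.character(rec$patient_id), as.character(res$patient_id)))
      exp <- res$experience
      if (config$report_mode == "self_consistent") {
        rec$reported_course <- list(source = "series", values = exp)
        return(rec)
      }
      duration <- length(exp) - 1L
      amp <- max(abs(exp), 1)
      template_fit <- vapply(1:9, function(id)
        fit_percentage(exp, render_template(id, duration, amplitude = amp))$fit_percent,
        numeric(1))
      cls <- classify_segments(exp)
      corrupt <- stats::runif(length(cls)) < config$report_noise
      labels <- c("decreasing", "constant", "increasing")
      cls[corrupt] <- vapply(cls[corrupt],
                             function(x) sample(setdiff(labels, x), 1), character(1))
      step <- c(decreasing = -10, constant = 0, increasing = 10)
      rec$reported_course <- list(source = "series",
                                  values = unname(cumsum(c(0, step[cls]))),
                                  template_id = unname(which.max(template_fit)))
      rec
    }, records, results)
  })
}

#' Marginal summary of a cohort of records
#'
#' The quantities the generator is calibrated against: medians, threshold
#' proportions and comorbidity prevalences.
#'
#' @param records list of patient records
#' @return list with `median_sleep_24h`, `pct_sleep_gt_660`, `pct_ess_gt_10`,
#'   `pct_mslt_lt_8`, `prevalence` (named vector over the calibrated
#'   comorbidities), `n`
#' @export
cohort_summary <- function(records) {
  sleep <- vapply(records, function(r) r$sleep_24h, numeric(1))
  ess <- vapply(records, function(r) r$ess_onset, numeric(1))
  mslt <- vapply(records, function(r) r$mslt_latency, numeric(1))
  prev_names <- names(default_comorbidity_prevalence())
  prevalence <- vapply(prev_names, function(nm)
    mean(vapply(records, function(r) !is.null(r$parameters[[nm]]), logical(1))),
    numeric(1))
  list(median_sleep_24h = stats::median(sleep),
       pct_sleep_gt_660 = 100 * mean(sleep > 660),
       pct_ess_gt_10 = 100 * mean(ess > 10),
       pct_mslt_lt_8 = 100 * mean(mslt < 8),
       prevalence = prevalence,
       n = length(records))
}
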