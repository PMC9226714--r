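# record validation shared by read_patients() and build_patient_model()
validate_record <- function(record, registry, index = NA) {
  where <- if (is.na(index)) {
    paste0("patient '", record$patient_id %||% "?", "'")
  } else {
    paste0("record #", index, " ('", record$patient_id %||% "?", "')")
  }
  problems <- character(0)
  if (is.null(record$patient_id)) problems <- c(problems, "missing patient_id")
  if (is.null(record$onset_year) || !is_year(record$onset_year))
    problems <- c(problems, "field onset_year: missing or not a year")
  if (is.null(record$interview_year) || !is_year(record$interview_year))
    problems <- c(problems, "field interview_year: missing or not a year")
  if (is_year(record$onset_year %||% NA) && is_year(record$interview_year %||% NA) &&
      record$interview_year < record$onset_year)
    problems <- c(problems, "field interview_year: earlier than onset_year")
  unknown <- setdiff(names(record$parameters %||% list()), registry$name)
  if (length(unknown))
    problems <- c(problems, paste0("field parameters: unknown name(s) ",
                                   paste(unknown, collapse = ", ")))
  for (nm in names(record$parameters %||% list())) {
    entry <- record$parameters[[nm]]
    has_static <- !is.null(entry$static)
    has_dynamic <- !is.null(entry$first_occurrence_year)
    if (has_static == has_dynamic)
      problems <- c(problems, paste0("field parameters.", nm,
                                     ": exactly one of static / dynamic spec required"))
  }
  unknown_med <- setdiff(names(record$medications %||% list()),
                         c("methylphenidate", "modafinil"))
  if (length(unknown_med))
    problems <- c(problems, paste0("field medications: unknown drug(s) ",
                                   paste(unknown_med, collapse = ", ")))
  if (length(problems))
    abort_ih(where, ":\n  - ", paste(problems, collapse = "\n  - "),
             class = "ihsim_validation_error")
  invisible(record)
}

#' Read and validate patient records
#'
#' Records are a YAML document: a sequence of nested per-patient mappings
#' (`patient_id`, `onset_year`, `interview_year`, `parameters`,
#' `medications`, `reported_course`, ...). Every record is validated against
#' the registry; failures are reported with the record index and field.
#'
#' @param path YAML file of patient records
#' @param registry an `ih_registry`
#' @return list of validated patient records
#' @export
read_patients <- function(path, registry = default_registry()) {
  if (!file.exists(path)) abort_ih("patient file not found: ", path)
  records <- yaml::read_yaml(path)
  if (!length(records))
    abort_ih("no patients in ", path, class = "ihsim_validation_error")
  errors <- character(0)
  for (i in seq_along(records)) {
    tryCatch(validate_record(records[[i]], registry, index = i),
             ihsim_validation_error = function(e) {
               errors <<- c(errors, conditionMessage(e))
             })
  }
  if (length(errors))
    abort_ih("patient file ", path, " failed validation:\n",
             paste(errors, collapse = "\n"), class = "ihsim_validation_error")
  records
}

#' Write patient records as YAML
#'
#' @param records list of patient records
#' @param path output file
#' @return `path`, invisibly
#' @export
write_patients <- function(records, path) {
  yaml::write_yaml(records, path, precision = 12)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles everything one run needs. Either `patients` (a YAML file path) or
#' `synthetic` (a [generator_config()]) supplies the cohort.
#'
#' @param out_dir output directory (created if absent)
#' @param patients path to a patient record file, or `NULL`
#' @param synthetic a [generator_config()], or `NULL`
#' @param registry_path registry CSV; default the shipped registry
#' @param scenarios character vector of scenario names to evaluate
#' @param seed integer seed recorded in all outputs
#' @param rate_cap_mode,experience_delay engine options, see [sim_config()]
#' @param tolerance constancy threshold for segment classification (`NULL`
#'   for the 1%-of-range default)
#' @return object of class `run_config`
#' @export
run_config <- function(out_dir, patients = NULL, synthetic = NULL,
                       registry_path = NULL,
                       scenarios = c("baseline", "last5", "medicated_only"),
                       seed = 1L, rate_cap_mode = "symmetric",
                       experience_delay = 1, tolerance = NULL) {
  if (is.null(patients) == is.null(synthetic))
    abort_ih("run_config: supply exactly one of patients / synthetic")
  if (!is.null(patients) && !file.exists(patients))
    abort_ih("run_config: patient file not found: ", patients)
  if (!is.null(registry_path) && !file.exists(registry_path))
    abort_ih("run_config: registry file not found: ", registry_path)
  structure(
    list(out_dir = out_dir, patients = patients, synthetic = synthetic,
         registry_path = registry_path, scenarios = scenarios,
         seed = as.integer(seed), rate_cap_mode = rate_cap_mode,
         experience_delay = experience_delay, tolerance = tolerance),
    class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "ihsim_error")) stop(e)
    abort_ih("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full simulation-and-analysis pipeline
#'
#' Loads or generates the cohort, builds and simulates every patient model,
#' attaches reported courses (synthetic cohorts), computes per-patient and
#' pooled derivative-sign fits, windows the configured scenarios, and writes
#' trajectories, fits, contribution tables, the scenario comparison, a
#' combined report and a machine-readable run manifest under `out_dir`.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with `records`, `models`, `results`, `fits`,
#'   `pooled_fit`, `scenarios` (windowed results), `tables`, `comparison`
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- stage("registry",
    if (is.null(config$registry_path)) default_registry()
    else read_registry(config$registry_path))

  records <- stage("cohort",
    if (!is.null(config$patients)) read_patients(config$patients, registry)
    else sample_cohort(config = config$synthetic, registry = registry))

  models <- stage("models",
    lapply(records, build_patient_model, registry = registry))
  sim_cfg <- function(m) {
    cfg <- sim_config(m$onset_year, m$interview_year,
                      rate_cap_mode = config$rate_cap_mode,
                      experience_delay = config$experience_delay)
    cfg
  }
  results <- stage("simulation",
    lapply(models, function(m) simulate_patient(m, sim_cfg(m))))

  if (!is.null(config$synthetic)) {
    records <- stage("reports", attach_reports(records, results, config$synthetic))
    models <- Map(function(m, rec) {
      m$reported_course <- reported_series_from_record(rec, m$onset_year,
                                                       m$interview_year)
      m
    }, models, records)
  }

  fits <- stage("fit", Map(function(m, r) {
    if (is.null(m$reported_course)) return(NULL)
    fit_percentage(r$experience, m$reported_course,
                   tolerance = config$tolerance, patient_id = m$patient_id)
  }, models, results))
  fits <- Filter(Negate(is.null), fits)
  pooled <- if (length(fits)) cohort_fit(fits) else NA_real_

  scen_results <- stage("scenarios",
    lapply(stats::setNames(nm = config$scenarios), function(s)
      apply_scenario(results, models, s)))
  tables <- lapply(names(scen_results), function(s)
    contribution_table(scen_results[[s]], s))
  names(tables) <- names(scen_results)

  comparison <- NULL
  if (all(c("last5", "medicated_only") %in% names(scen_results)))
    comparison <- stage("comparison",
      compare_scenarios(scen_results$last5, scen_results$medicated_only,
                        groups = c("last5", "medicated_only")))

  # --- outputs ---------------------------------------------------------
  manifest <- list(
    package = "ihsim",
    version = as.character(utils::packageVersion("ihsim")),
    seed = config$seed,
    config = config[c("patients", "scenarios", "rate_cap_mode",
                      "experience_delay", "tolerance")],
    synthetic = if (is.null(config$synthetic)) NULL else
      unclass(config$synthetic),
    n_patients = length(records))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")

  traj <- do.call(rbind, lapply(results, as.data.frame))
  utils::write.csv(traj, file.path(config$out_dir, "trajectories.csv"),
                   row.names = FALSE)
  if (length(fits)) {
    fit_df <- do.call(rbind, lapply(fits, function(f)
      data.frame(patient_id = f$patient_id, n_segments = f$n_segments,
                 n_matches = f$n_matches, fit_percent = f$fit_percent)))
    fit_df$pooled_fit <- pooled
    utils::write.csv(fit_df, file.path(config$out_dir, "fits.csv"),
                     row.names = FALSE)
  }
  for (s in names(tables)) {
    tab <- tables[[s]]
    tab$n_patients <- attr(tab, "n_patients")
    utils::write.csv(tab, file.path(config$out_dir,
                                    paste0("contribution_", s, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(comparison))
    utils::write.csv(as.data.frame(comparison),
                     file.path(config$out_dir, "scenario_comparison.csv"),
                     row.names = FALSE)
  if (all(c("baseline", "last5", "medicated_only") %in% names(tables)))
    write_table4_report(tables, comparison,
                        file.path(config$out_dir, "contribution_report.csv"))

  invisible(list(records = records, models = models, results = results,
                 fits = fits, pooled_fit = pooled, scenarios = scen_results,
                 tables = tables, comparison = comparison))
}

#' Write the combined three-scenario contribution report
#'
#' One row per aggregate with the signed sum and absolute contribution
#' percentage for each of the three scenarios, plus the Mann-Whitney p-value
#' comparing the last-5-years and medicated-only scenarios — mirroring the
#' published summary layout. Percentages are rounded to one decimal.
#'
#' @param tables named list of `contribution_table`s; must contain
#'   `baseline`, `last5` and `medicated_only`
#' @param comparison a `scenario_comparison`, or `NULL` to omit the p column
#' @param path output CSV
#' @return the report data.frame, invisibly
#' @export
write_table4_report <- function(tables, comparison, path) {
  needed <- c("baseline", "last5", "medicated_only")
  missing <- setdiff(needed, names(tables))
  if (length(missing))
    abort_ih("report: missing scenario table(s): ", paste(missing, collapse = ", "))
  report <- data.frame(aggregate = tables$baseline$aggregate,
                       stringsAsFactors = FALSE)
  for (s in needed) {
    tab <- tables[[s]]
    if (!identical(tab$aggregate, report$aggregate))
      abort_ih("report: scenario '", s, "' rows out of order")
    report[[paste0(s, "_sum")]] <- round(tab$signed_sum, 2)
    report[[paste0(s, "_pct")]] <- tab$contribution_percent
  }
  if (!is.null(comparison)) {
    stopifnot(identical(comparison$aggregate, report$aggregate))
    report$p <- signif(comparison$p, 3)
  }
  utils::write.csv(report, path, row.names = FALSE)
  invisible(report)
}
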