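#' Names of the twelve output aggregates
#'
#' The simulation's outputs are not the 71 raw inputs but their logical
#' aggregation into twelve clinical state variables.
#'
#' @return character vector of length 12
#' @export
aggregate_names <- function() {
  c("Anxiety", "Depression", "Sleep inertia", "Work and social impairment",
    "Sleepiness", "Fatigue", "Naps", "Nocturnal sleep",
    "Other psychiatric disorders", "Somatic pathologies",
    "Methylphenidate effect", "Modafinil effect")
}

# default adjustment times per aggregate, in years: slow-moving comorbidity
# burdens adjust over ~3 years, core sleep symptoms over ~2, and medication
# effects within a single year
default_aggregate_delays <- function() {
  c("Anxiety" = 2, "Depression" = 3, "Sleep inertia" = 2,
    "Work and social impairment" = 3, "Sleepiness" = 2, "Fatigue" = 2,
    "Naps" = 1, "Nocturnal sleep" = 2, "Other psychiatric disorders" = 3,
    "Somatic pathologies" = 3, "Methylphenidate effect" = 1,
    "Modafinil effect" = 1)
}

#' Read and validate a parameter registry
#'
#' The registry is a delimited table with one row per model input parameter:
#' `name`, `kind`, `scale_min`, `scale_max`, `polarity`, `aggregate`. It must
#' partition its parameters over the twelve aggregates (every parameter in
#' exactly one aggregate, no aggregate empty).
#'
#' @param path CSV file; `#` lines are comments
#' @return data.frame of class `ih_registry`
#' @export
read_registry <- function(path) {
  reg <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("name", "kind", "scale_min", "scale_max", "polarity", "aggregate")
  missing <- setdiff(needed, names(reg))
  if (length(missing))
    abort_ih("registry ", path, ": missing column(s) ", paste(missing, collapse = ", "))
  problems <- character(0)
  dup <- reg$name[duplicated(reg$name)]
  if (length(dup))
    problems <- c(problems, paste0("duplicated parameter name(s): ",
                                   paste(unique(dup), collapse = ", ")))
  bad_kind <- !reg$kind %in% c("continuous", "ordinal", "nominal", "binary")
  if (any(bad_kind))
    problems <- c(problems, paste0("row ", which(bad_kind), " (", reg$name[bad_kind],
                                   "): unknown kind '", reg$kind[bad_kind], "'"))
  bad_pol <- !reg$polarity %in% c("always_negative", "always_positive", "data_dependent")
  if (any(bad_pol))
    problems <- c(problems, paste0("row ", which(bad_pol), " (", reg$name[bad_pol],
                                   "): unknown polarity '", reg$polarity[bad_pol], "'"))
  bad_agg <- !reg$aggregate %in% aggregate_names()
  if (any(bad_agg))
    problems <- c(problems, paste0("row ", which(bad_agg), " (", reg$name[bad_agg],
                                   "): unknown aggregate '", reg$aggregate[bad_agg], "'"))
  empty <- setdiff(aggregate_names(), reg$aggregate)
  if (length(empty))
    problems <- c(problems, paste0("aggregate(s) with no member parameters: ",
                                   paste(empty, collapse = ", ")))
  bad_scale <- is.finite(reg$scale_min) & is.finite(reg$scale_max) &
    reg$scale_min >= reg$scale_max
  if (any(bad_scale))
    problems <- c(problems, paste0("row ", which(bad_scale), " (", reg$name[bad_scale],
                                   "): degenerate scale"))
  if (length(problems))
    abort_ih("registry validation failed:\n  - ", paste(problems, collapse = "\n  - "),
             class = "ihsim_validation_error")
  class(reg) <- c("ih_registry", "data.frame")
  reg
}

#' The registry shipped with the package
#'
#' 71 parameters partitioned over the twelve aggregates, with the published
#' member counts for Somatic pathologies (24) and Naps (6).
#'
#' @return data.frame of class `ih_registry`
#' @export
default_registry <- function() {
  read_registry(system.file("extdata", "parameter_registry.csv",
                            package = "ihsim", mustWork = TRUE))
}

registry_parameter <- function(registry, name) {
  row <- registry[registry$name == name, , drop = FALSE]
  if (nrow(row) != 1L) abort_ih("unknown registry parameter '", name, "'")
  raw_parameter(
    name = row$name, kind = row$kind,
    scale_min = if (is.finite(row$scale_min)) row$scale_min else NULL,
    scale_max = if (is.finite(row$scale_max)) row$scale_max else NULL,
    polarity = row$polarity)
}

#' Combine member schedules into an aggregate target schedule
#'
#' Per-year targets of the member parameters are combined by mean (default,
#' preserving the common scale) or sum, and clamped to \[-100, 100\].
#'
#' @param member_schedules non-empty list of [target_schedule()]s on a shared
#'   year axis
#' @param rule `"mean"` or `"sum"`
#' @param name name for the combined schedule
#' @return a [target_schedule()]
#' @export
aggregate_schedule <- function(member_schedules, rule = c("mean", "sum"),
                               name = "aggregate") {
  rule <- match.arg(rule)
  if (!length(member_schedules)) abort_ih("aggregate '", name, "': empty member list")
  years <- member_schedules[[1]]$years
  for (s in member_schedules)
    if (!identical(s$years, years))
      abort_ih("aggregate '", name, "': member schedules have mismatched year axes")
  mat <- vapply(member_schedules, function(s) s$targets, numeric(length(years)))
  mat <- matrix(mat, nrow = length(years))
  g <- if (rule == "mean") rowMeans(mat) else rowSums(mat)
  target_schedule(name, years, clamp(g, -100, 100))
}

# reconstruct the patient-reported course as a yearly series over the window
reported_series_from_record <- function(record, onset_year, interview_year,
                                        amplitude = 80) {
  rc <- record$reported_course
  if (is.null(rc)) return(NULL)
  years <- onset_year:interview_year
  duration <- interview_year - onset_year
  if (identical(rc$source, "template")) {
    render_template(rc$template_id, duration, amplitude = amplitude)
  } else if (identical(rc$source, "custom_drawn")) {
    ay <- vapply(rc$anchors, function(a) as.numeric(a$year), numeric(1))
    av <- vapply(rc$anchors, function(a) as.numeric(a$value), numeric(1))
    stats::approx(ay, av, xout = years, method = "linear", rule = 2)$y
  } else if (identical(rc$source, "series")) {
    if (length(rc$values) != length(years))
      abort_ih("patient '", record$patient_id, "': reported series length ",
               length(rc$values), " does not span onset-interview (",
               length(years), " years)")
    as.numeric(rc$values)
  } else {
    abort_ih("patient '", record$patient_id, "': unknown reported_course source '",
             rc$source, "'")
  }
}

#' Assemble a simulation-ready model for one patient
#'
#' Dynamizes every registry parameter present in the record into a target
#' schedule (absent phenomena become zero schedules), combines members into
#' the twelve aggregate schedules, attaches per-aggregate delays and the
#' reported course.
#'
#' @param record one validated patient record (see [read_patients()])
#' @param registry an `ih_registry`
#' @param combine_rule aggregate combination rule, `"mean"` or `"sum"`
#' @param mode between-event interpolation, `"step"` or `"linear"`
#' @param persistence post-discontinuation medication persistence, years
#' @param delays named per-aggregate adjustment times (years); defaults to
#'   the package's clinical defaults, overridden by any `delays` entry in the
#'   record
#' @return object of class `patient_model`
#' @export
build_patient_model <- function(record, registry = default_registry(),
                                combine_rule = c("mean", "sum"),
                                mode = c("step", "linear"),
                                persistence = 1,
                                delays = default_aggregate_delays()) {
  combine_rule <- match.arg(combine_rule)
  mode <- match.arg(mode)
  validate_record(record, registry)
  onset <- record$onset_year
  interview <- record$interview_year

  medication_params <- registry$name[registry$aggregate %in%
                                       c("Methylphenidate effect", "Modafinil effect")]
  med_key <- c(methylphenidate_effect = "methylphenidate",
               modafinil_effect = "modafinil")

  schedules <- vector("list", nrow(registry))
  names(schedules) <- registry$name
  for (nm in registry$name) {
    proto <- registry_parameter(registry, nm)
    if (nm %in% medication_params) {
      episodes <- record$medications[[med_key[[nm]]]] %||% list()
      schedules[[nm]] <- build_medication_schedule(episodes, proto, onset, interview,
                                                   persistence = persistence)
    } else {
      entry <- record$parameters[[nm]]
      if (is.null(entry)) {
        schedules[[nm]] <- zero_schedule(nm, onset, interview)
      } else {
        par <- record_entry_to_parameter(proto, entry)
        schedules[[nm]] <- build_target_schedule(par, onset, interview, mode = mode)
      }
    }
  }

  agg_schedules <- lapply(stats::setNames(nm = aggregate_names()), function(a) {
    members <- registry$name[registry$aggregate == a]
    aggregate_schedule(schedules[members], rule = combine_rule, name = a)
  })

  delays <- utils::modifyList(as.list(delays), as.list(record$delays %||% list()))

  med_flags <- lapply(stats::setNames(nm = c("methylphenidate", "modafinil")),
                      function(drug) {
    eps <- record$medications[[drug]] %||% list()
    lapply(eps, function(e) list(start_year = e$start_year, stop_year = e$stop_year))
  })

  structure(
    list(patient_id = record$patient_id,
         onset_year = onset, interview_year = interview,
         parameter_schedules = schedules,
         aggregate_schedules = agg_schedules,
         aggregate_delays = delays,
         initial_values = as.list(record$initial_values %||% list()),
         reported_course = reported_series_from_record(record, onset, interview),
         medication_flags = med_flags),
    class = "patient_model")
}

# turn a record's parameter entry (static scalar or dynamic spec fields)
# into a value-carrying raw_parameter
record_entry_to_parameter <- function(proto, entry) {
  if (!is.null(entry$static)) {
    proto$static_value <- entry$static
    proto$perceived_positive <- entry$perceived_positive %||% NULL
    return(proto)
  }
  events <- lapply(entry$change_events %||% list(), function(e)
    list(year = e$year, value = e$value, rate = e$rate %||% "step"))
  proto$dynamic_spec <- dynamic_spec(
    first_occurrence_year = entry$first_occurrence_year,
    last_occurrence_year = entry$last_occurrence_year %||% NULL,
    max_value = entry$max_value,
    min_value = entry$min_value %||% 0,
    change_events = events,
    perceived_positive = entry$perceived_positive %||% NULL)
  proto
}

#' Analysis scenario definition
#'
#' * `baseline`: every patient, the full disease duration.
#' * `last5`: the final five years of each trajectory; patients with disease
#'   duration under five years are excluded.
#' * `medicated_only`: the `last5` window restricted to patients with a
#'   methylphenidate or modafinil episode overlapping that window.
#'
#' @param name scenario name
#' @param min_duration minimum disease duration (years) for the 5-year
#'   windows
#' @return object of class `scenario_spec`
#' @export
scenario_spec <- function(name = c("baseline", "last5", "medicated_only"),
                          min_duration = 5) {
  name <- match.arg(name)
  structure(list(name = name, min_duration = min_duration,
                 window_years = if (name == "baseline") NULL else 5L),
            class = "scenario_spec")
}

medicated_in_window <- function(model, win_start, win_end) {
  for (drug in model$medication_flags)
    for (e in drug)
      if (e$start_year <= win_end && e$stop_year + 1 >= win_start) return(TRUE)
  FALSE
}

#' Window simulation results for a scenario
#'
#' Selects patients and clips trajectories; never alters values. The 5-year
#' window keeps the last five yearly values of each trajectory (years after
#' interview - 5).
#'
#' @param results list of `simulation_result`
#' @param models list of `patient_model`, aligned by patient_id
#' @param scenario a [scenario_spec()] or scenario name
#' @return list of windowed `simulation_result`s
#' @export
apply_scenario <- function(results, models, scenario) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  ids <- vapply(models, function(m) as.character(m$patient_id), character(1))
  names(models) <- ids
  out <- list()
  for (res in results) {
    model <- models[[as.character(res$patient_id)]]
    if (is.null(model))
      abort_ih("scenario '", scenario$name, "': no model for patient '",
               res$patient_id, "'")
    if (scenario$name == "baseline") {
      out[[length(out) + 1L]] <- res
      next
    }
    duration <- model$interview_year - model$onset_year
    if (duration < scenario$min_duration) next
    win_start <- model$interview_year - scenario$window_years + 1L
    if (scenario$name == "medicated_only" &&
        !medicated_in_window(model, model$interview_year - scenario$window_years + 1L,
                             model$interview_year)) next
    keep <- res$years >= win_start
    res$years <- res$years[keep]
    res$aggregates <- res$aggregates[keep, , drop = FALSE]
    res$experience <- res$experience[keep]
    out[[length(out) + 1L]] <- res
  }
  if (!length(out))
    abort_ih("scenario '", scenario$name, "': no patients selected")
  out
}
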