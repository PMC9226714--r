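#' Adjustment-time delay of a feedback level
#'
#' The delay (adjustment time) d sets how fast a level closes the gap to its
#' target: each year the level moves by (target - value)/d, subject to the
#' rate cap.
#'
#' @param adjustment_time years, > 0
#' @return an object of class `delay_spec`
#' @export
delay_spec <- function(adjustment_time) {
  if (!is.numeric(adjustment_time) || length(adjustment_time) != 1L ||
      !is.finite(adjustment_time) || adjustment_time <= 0)
    abort_ih("adjustment_time must be a single positive number")
  structure(list(adjustment_time = adjustment_time), class = "delay_spec")
}

#' Simulation configuration
#'
#' The clock runs in whole years from disease onset to the re-evaluation
#' interview. `rate_cap_mode` selects how the per-step inflow is capped by
#' the target (see [step_rate()]); `experience_delay` is the adjustment time
#' of the overall-experience loop.
#'
#' @param start_year,end_year calendar years bounding the simulated period
#' @param rate_cap_mode `"symmetric"` (default; target-seeking for targets of
#'   either sign) or `"literal"` (the signed MIN cap as printed, which repels
#'   the level from negative targets)
#' @param experience_delay years, adjustment time of the experience level
#' @return an object of class `sim_config`
#' @export
sim_config <- function(start_year, end_year,
                       rate_cap_mode = c("symmetric", "literal"),
                       experience_delay = 1) {
  rate_cap_mode <- match.arg(rate_cap_mode)
  if (!is_year(start_year) || !is_year(end_year) || end_year < start_year)
    abort_ih("invalid simulation window [", start_year, ", ", end_year, "]")
  structure(
    list(start_year = start_year, end_year = end_year, step_years = 1L,
         rate_cap_mode = rate_cap_mode, experience_delay = experience_delay),
    class = "sim_config")
}

#' One-step rate of a target-seeking level
#'
#' The raw adjustment rate is the goal gap divided by the adjustment time,
#' (g - PV)/d, capped by the target value. In `"literal"` mode the cap is the
#' signed minimum MIN(raw, g); in `"symmetric"` mode the cap acts on
#' magnitudes, sign(raw) * MIN(|raw|, |g|) (for g = 0 the raw rate is used),
#' so that levels approach negative targets instead of overshooting them.
#'
#' @param level_value current level value PV
#' @param target current target g
#' @param delay a [delay_spec()] (or a bare positive number of years)
#' @param mode `"symmetric"` or `"literal"`
#' @return list with `inflow`, `target`, `gap`
#' @export
step_rate <- function(level_value, target, delay, mode = c("symmetric", "literal")) {
  mode <- match.arg(mode)
  d <- if (inherits(delay, "delay_spec")) delay$adjustment_time else delay
  if (!is.finite(level_value) || !is.finite(target) || !is.finite(d) || d <= 0)
    abort_ih("step_rate: non-finite input or non-positive delay")
  raw <- (target - level_value) / d
  inflow <- switch(mode,
    literal = min(raw, target),
    symmetric = if (target != 0) sign(raw) * min(abs(raw), abs(target)) else raw)
  list(inflow = inflow, target = target, gap = target - level_value)
}

#' Integrate one feedback level over the simulated period
#'
#' Explicit Euler at the model's one-year step: PV_{t+1} = PV_t +
#' step_rate(PV_t, g_t, d). The trajectory carries one value per year from
#' the start of the window to its end (steps + 1 points), beginning at the
#' initial value.
#'
#' @param initial_value level value at the start of the window
#' @param schedule a [target_schedule()] covering the window
#' @param delay a [delay_spec()] or bare adjustment time in years
#' @param config a [sim_config()]
#' @param name level name (defaults to the schedule's parameter name)
#' @return object of class `state_level` with `name`, `initial_value`,
#'   `years`, `trajectory`
#' @export
integrate_level <- function(initial_value, schedule, delay, config,
                            name = schedule$parameter_name) {
  years <- config$start_year:config$end_year
  idx <- match(years, schedule$years)
  if (anyNA(idx))
    abort_ih("level '", name, "': schedule does not cover the simulated window")
  g <- schedule$targets[idx]
  n <- length(years) - 1L
  pv <- numeric(n + 1L)
  pv[1] <- initial_value
  for (t in seq_len(n))
    pv[t + 1L] <- pv[t] + step_rate(pv[t], g[t], delay, config$rate_cap_mode)$inflow
  structure(
    list(name = name, initial_value = initial_value,
         years = years, trajectory = pv),
    class = "state_level")
}

# integrate against an explicit per-year target vector (used for the
# experience loop whose target is the running sum of the aggregate levels)
integrate_series <- function(initial_value, years, targets, delay, mode) {
  n <- length(years) - 1L
  pv <- numeric(n + 1L)
  pv[1] <- initial_value
  for (t in seq_len(n))
    pv[t + 1L] <- pv[t] + step_rate(pv[t], targets[t], delay, mode)$inflow
  pv
}

#' Simulate one patient's full model
#'
#' Integrates the twelve aggregate clinical levels against their dynamized
#' target schedules, then integrates the overall-experience level, a
#' negative-feedback loop whose per-step target is the sum of all twelve
#' aggregate values at that step.
#'
#' @param model a `patient_model` (see [build_patient_model()])
#' @param config a [sim_config()]; defaults to the patient's onset-interview
#'   window with symmetric rate capping
#' @return object of class `simulation_result`: `patient_id`, `years`,
#'   `aggregates` (years x 12 matrix), `experience`
#' @export
simulate_patient <- function(model, config = NULL) {
  if (is.null(config))
    config <- sim_config(model$onset_year, model$interview_year)
  aggs <- aggregate_names()
  missing <- setdiff(aggs, names(model$aggregate_schedules))
  if (length(missing))
    abort_ih("patient '", model$patient_id, "': missing aggregate schedule(s): ",
             paste(missing, collapse = ", "))
  years <- config$start_year:config$end_year
  traj <- matrix(NA_real_, nrow = length(years), ncol = length(aggs),
                 dimnames = list(NULL, aggs))
  for (a in aggs) {
    lev <- integrate_level(
      initial_value = model$initial_values[[a]] %||% 0,
      schedule = model$aggregate_schedules[[a]],
      delay = model$aggregate_delays[[a]] %||% 1,
      config = config, name = a)
    traj[, a] <- lev$trajectory
  }
  exp_target <- rowSums(traj)
  experience <- integrate_series(0, years, exp_target, config$experience_delay,
                                 config$rate_cap_mode)
  structure(
    list(patient_id = model$patient_id, years = years,
         aggregates = traj, experience = experience),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> patient ", x$patient_id, ": years ",
      min(x$years), "-", max(x$years), ", experience range [",
      round(min(x$experience), 1), ", ", round(max(x$experience), 1), "]\n",
      sep = "")
  invisible(x)
}

#' Tidy long-format view of a simulation result
#'
#' @param x a `simulation_result`
#' @param row.names,optional,... ignored (S3 conformance)
#' @return data.frame with columns `patient_id`, `year`, `variable`, `value`
#' @export
as.data.frame.simulation_result <- function(x, row.names = NULL, optional = FALSE, ...) {
  vars <- c(colnames(x$aggregates), "experience")
  data.frame(
    patient_id = x$patient_id,
    year = rep(x$years, times = length(vars)),
    variable = rep(vars, each = length(x$years)),
    value = c(as.vector(x$aggregates), x$experience),
    stringsAsFactors = FALSE)
}
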