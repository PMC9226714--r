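#' Clinical input parameter definition
#'
#' Describes one interview-derived model input: its measurement kind, native
#' instrument scale, and the polarity rule that decides the sign its target
#' schedule takes on the common \[-100, 100\] scale. Some phenomena are
#' experienced as negative whenever present (depression, pain); others, such
#' as naps, are positive when the patient perceived them as refreshing and
#' negative otherwise (`data_dependent`).
#'
#' A parameter may carry a value in one of two mutually exclusive forms:
#' `static_value` (a single native-units value, constant over the disease
#' course) or `dynamic_spec` (see [dynamic_spec()]). Registry prototypes
#' carry neither; the value is attached per patient.
#'
#' @param name parameter identifier
#' @param kind one of `"continuous"`, `"ordinal"`, `"nominal"`, `"binary"`
#' @param scale_min,scale_max native instrument range (e.g. 0 and 24 for the
#'   Epworth Sleepiness Scale); may be `NULL` when a cohort-observed range is
#'   supplied at normalization time
#' @param polarity one of `"always_negative"`, `"always_positive"`,
#'   `"data_dependent"`
#' @param static_value native-units value for a static parameter
#' @param dynamic_spec a [dynamic_spec()] for a dynamic parameter
#' @param perceived_positive logical; required to resolve the sign when
#'   `polarity = "data_dependent"`
#' @return an object of class `raw_parameter`
#' @export
raw_parameter <- function(name, kind = c("continuous", "ordinal", "nominal", "binary"),
                          scale_min = NULL, scale_max = NULL,
                          polarity = c("always_negative", "always_positive", "data_dependent"),
                          static_value = NULL, dynamic_spec = NULL,
                          perceived_positive = NULL) {
  kind <- match.arg(kind)
  polarity <- match.arg(polarity)
  if (!is.null(static_value) && !is.null(dynamic_spec))
    abort_ih("parameter '", name, "': static_value and dynamic_spec are mutually exclusive")
  if (!is.null(scale_min) && !is.null(scale_max) && scale_min >= scale_max)
    abort_ih("parameter '", name, "': degenerate scale (scale_min >= scale_max)")
  structure(
    list(name = name, kind = kind,
         scale_min = scale_min, scale_max = scale_max,
         polarity = polarity,
         static_value = static_value, dynamic_spec = dynamic_spec,
         perceived_positive = perceived_positive),
    class = "raw_parameter")
}

#' Dynamic specification of a parameter's course
#'
#' The uniform structure in which the interview captures a phenomenon's
#' history: year of first occurrence, extreme values, year of last occurrence
#' (if it resolved), and dated change events that move the target value.
#'
#' @param first_occurrence_year calendar year the phenomenon first appeared
#' @param last_occurrence_year calendar year it resolved, or `NULL` if still
#'   present at interview
#' @param max_value,min_value extreme values in native units
#' @param change_events list of events, each a list with elements `year`,
#'   `value` (native units) and optionally `rate` (`"step"` or `"linear"`);
#'   must be sorted by year
#' @param perceived_positive logical, resolves `data_dependent` polarity
#' @return an object of class `dynamic_spec`
#' @export
dynamic_spec <- function(first_occurrence_year, last_occurrence_year = NULL,
                         max_value, min_value = 0, change_events = list(),
                         perceived_positive = NULL) {
  if (!is_year(first_occurrence_year))
    abort_ih("first_occurrence_year must be a single year")
  if (!is.null(last_occurrence_year)) {
    if (!is_year(last_occurrence_year))
      abort_ih("last_occurrence_year must be a single year or NULL")
    if (first_occurrence_year > last_occurrence_year)
      abort_ih("first_occurrence_year exceeds last_occurrence_year")
  }
  if (min_value > max_value) abort_ih("min_value exceeds max_value")
  if (length(change_events)) {
    yrs <- vapply(change_events, function(e) as.numeric(e$year), numeric(1))
    if (is.unsorted(yrs, strictly = FALSE))
      abort_ih("change_events must be sorted by year")
  }
  structure(
    list(first_occurrence_year = first_occurrence_year,
         last_occurrence_year = last_occurrence_year,
         max_value = max_value, min_value = min_value,
         change_events = change_events,
         perceived_positive = perceived_positive),
    class = "dynamic_spec")
}

#' Per-year target schedule on the common scale
#'
#' Holds the dynamized goal values g_t in \[-100, 100\] for one parameter,
#' split into a non-negative increasing component (IF) and decreasing
#' component (DF) with g_t = IF_t - DF_t.
#'
#' @param parameter_name identifier
#' @param years ordered integer simulation years
#' @param targets per-year target values, |g_t| <= 100
#' @return an object of class `target_schedule`
#' @export
target_schedule <- function(parameter_name, years, targets) {
  if (length(years) != length(targets))
    abort_ih("schedule '", parameter_name, "': years and targets differ in length")
  if (length(years) && is.unsorted(years, strictly = TRUE))
    abort_ih("schedule '", parameter_name, "': years must be strictly increasing")
  if (any(!is.finite(targets)) || any(abs(targets) > 100 + 1e-9))
    abort_ih("schedule '", parameter_name, "': targets must be finite and within [-100, 100]")
  structure(
    list(parameter_name = parameter_name,
         years = as.integer(years),
         targets = as.numeric(targets),
         increasing = pmax(targets, 0),
         decreasing = pmax(-targets, 0)),
    class = "target_schedule")
}

#' @export
print.target_schedule <- function(x, ...) {
  cat("<target_schedule> ", x$parameter_name, ": ",
      length(x$years), " years [", min(x$years), "-", max(x$years), "], ",
      "range [", round(min(x$targets), 2), ", ", round(max(x$targets), 2), "]\n",
      sep = "")
  invisible(x)
}

#' Normalize a native-units value to the common 0-100 scale
#'
#' Continuous and ordinal values map linearly from the instrument scale onto
#' \[0, 100\] (ordinal categories land evenly spaced); binary and nominal
#' presence/absence map to 0 or 100. Values outside the declared scale are
#' clamped with a warning — interview data plausibly contains mild
#' out-of-range entries.
#'
#' @param raw native-units value
#' @param parameter a [raw_parameter()]
#' @param cohort_range length-2 numeric fallback range when the parameter
#'   declares no instrument scale
#' @return value in \[0, 100\]
#' @export
normalize_value <- function(raw, parameter, cohort_range = NULL) {
  if (!is.finite(raw)) abort_ih("parameter '", parameter$name, "': non-finite raw value")
  if (parameter$kind %in% c("binary", "nominal"))
    return(if (raw != 0) 100 else 0)
  lo <- parameter$scale_min
  hi <- parameter$scale_max
  if (is.null(lo) || is.null(hi)) {
    if (is.null(cohort_range))
      abort_ih("parameter '", parameter$name,
               "': no instrument scale declared and no cohort range supplied")
    lo <- cohort_range[1]
    hi <- cohort_range[2]
  }
  if (lo >= hi) abort_ih("parameter '", parameter$name, "': degenerate scale")
  if (raw < lo || raw > hi) {
    warning("parameter '", parameter$name, "': value ", raw,
            " outside scale [", lo, ", ", hi, "], clamped", call. = FALSE)
    raw <- clamp(raw, lo, hi)
  }
  100 * (raw - lo) / (hi - lo)
}

# resolve the sign a parameter's targets take on the common scale
schedule_sign <- function(parameter, perceived_positive = NULL) {
  switch(parameter$polarity,
    always_negative = -1,
    always_positive = +1,
    data_dependent = {
      pp <- perceived_positive %||% parameter$perceived_positive
      if (is.null(pp) || is.na(pp))
        abort_ih("parameter '", parameter$name,
                 "': polarity is data_dependent but no perception flag supplied")
      if (isTRUE(pp)) +1 else -1
    })
}

#' Dynamize a parameter into a per-year target schedule
#'
#' Converts an interview parameter (static value or dynamic history) into the
#' yearly goal series g_t driving its feedback level. Before the first
#' occurrence and after the last occurrence the target is 0; between them the
#' normalized extreme value holds, stepping (or ramping, `mode = "linear"`)
#' through any dated change events. The polarity rule assigns the sign.
#'
#' @param parameter a [raw_parameter()] carrying `static_value` or
#'   `dynamic_spec`
#' @param onset_year first simulated year (disease onset)
#' @param horizon_year last simulated year (re-evaluation interview)
#' @param mode interpolation between change events: `"step"`
#'   (piecewise-constant, default) or `"linear"` (ramp)
#' @param cohort_range optional fallback scale, see [normalize_value()]
#' @return a [target_schedule()] spanning `onset_year:horizon_year`
#' @export
build_target_schedule <- function(parameter, onset_year, horizon_year,
                                  mode = c("step", "linear"), cohort_range = NULL) {
  mode <- match.arg(mode)
  if (!is_year(onset_year) || !is_year(horizon_year) || horizon_year < onset_year)
    abort_ih("invalid simulation window [", onset_year, ", ", horizon_year, "]")
  years <- onset_year:horizon_year
  g <- numeric(length(years))

  if (is.null(parameter$static_value) && is.null(parameter$dynamic_spec))
    abort_ih("parameter '", parameter$name, "': no value attached (static or dynamic)")

  if (!is.null(parameter$static_value)) {
    mag <- normalize_value(parameter$static_value, parameter, cohort_range)
    sgn <- schedule_sign(parameter)
    return(target_schedule(parameter$name, years, rep(sgn * mag, length(years))))
  }

  spec <- parameter$dynamic_spec
  first <- spec$first_occurrence_year
  last <- spec$last_occurrence_year %||% horizon_year
  if (first > horizon_year || last < onset_year)
    return(target_schedule(parameter$name, years, g))
  if (length(spec$change_events)) {
    ev_years <- vapply(spec$change_events, function(e) as.numeric(e$year), numeric(1))
    if (any(ev_years < first) || any(ev_years > min(last, horizon_year)))
      abort_ih("parameter '", parameter$name,
               "': change event outside the active window [", first, ", ",
               min(last, horizon_year), "]")
  }
  sgn <- schedule_sign(parameter, spec$perceived_positive)

  # anchors: (year, magnitude) points the target passes through, starting at
  # the normalized extreme value at first occurrence unless an event says
  # otherwise at that very year
  anchors_y <- first
  anchors_v <- normalize_value(spec$max_value, parameter, cohort_range)
  for (e in spec$change_events) {
    v <- normalize_value(e$value, parameter, cohort_range)
    if (e$year == first) {
      anchors_v[1] <- v
    } else {
      anchors_y <- c(anchors_y, e$year)
      anchors_v <- c(anchors_v, v)
    }
  }

  active <- years >= first & years <= last
  yrs_active <- years[active]
  if (mode == "step" || length(anchors_y) == 1L) {
    idx <- findInterval(yrs_active, anchors_y)
    g[active] <- anchors_v[idx]
  } else {
    g[active] <- stats::approx(anchors_y, anchors_v, xout = yrs_active,
                               method = "linear", rule = 2)$y
  }
  target_schedule(parameter$name, years, sgn * g)
}

#' Dynamize medication episodes into a target schedule
#'
#' During administration the target equals the normalized perceived effect;
#' after discontinuation it decays linearly to zero over a short persistence
#' window (default one simulation year, i.e. the year after stopping carries
#' half the effect), and is zero outside episodes.
#'
#' @param episodes list of episodes, each a list with `start_year`,
#'   `stop_year`, `effect` (native units, magnitude) and optionally
#'   `perceived_positive`; must be sorted and non-overlapping
#' @param parameter the medication-effect [raw_parameter()]
#' @param onset_year,horizon_year simulation window
#' @param persistence post-discontinuation persistence in years
#' @return a [target_schedule()]
#' @export
build_medication_schedule <- function(episodes, parameter, onset_year, horizon_year,
                                      persistence = 1) {
  years <- onset_year:horizon_year
  g <- numeric(length(years))
  if (length(episodes)) {
    starts <- vapply(episodes, function(e) as.numeric(e$start_year), numeric(1))
    stops <- vapply(episodes, function(e) as.numeric(e$stop_year), numeric(1))
    if (any(stops < starts)) abort_ih("medication episode with stop_year < start_year")
    if (length(episodes) > 1L) {
      if (is.unsorted(starts, strictly = TRUE))
        abort_ih("medication episodes must be sorted by start_year")
      if (any(starts[-1] <= stops[-length(stops)]))
        abort_ih("overlapping medication episodes")
    }
    for (e in episodes) {
      eff <- normalize_value(abs(e$effect), parameter)
      if (eff == 0) next
      sgn <- schedule_sign(parameter, e$perceived_positive %||% TRUE)
      on_years <- years >= e$start_year & years <= e$stop_year
      g[on_years] <- sgn * eff
      if (persistence > 0) {
        for (k in seq_len(persistence)) {
          yr <- e$stop_year + k
          i <- match(yr, years)
          if (!is.na(i)) g[i] <- sgn * eff * (persistence - k + 1) / (persistence + 1)
        }
      }
    }
  }
  target_schedule(parameter$name, years, g)
}

#' All-zero schedule over a window
#'
#' Used for parameters whose phenomenon never occurred in a patient.
#'
#' @inheritParams build_medication_schedule
#' @param parameter_name identifier
#' @return a [target_schedule()] of zeros
#' @export
zero_schedule <- function(parameter_name, onset_year, horizon_year) {
  years <- onset_year:horizon_year
  target_schedule(parameter_name, years, numeric(length(years)))
}
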