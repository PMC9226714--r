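#' Names of the nine predefined course patterns
#'
#' The interview asks each patient to pick, from nine plotted time-course
#' templates, the one best matching their experience of the disease.
#'
#' @return named character vector (names are the template ids 1-9)
#' @export
template_shapes <- function() {
  c("1" = "monotone worsening", "2" = "monotone improvement", "3" = "constant",
    "4" = "slight oscillation", "5" = "strong oscillation",
    "6" = "worsening-then-plateau", "7" = "improvement-then-plateau",
    "8" = "worsening-then-improvement", "9" = "improvement-then-worsening")
}

#' Render a reported-course template as a yearly series
#'
#' Canonical stand-ins for the nine plotted patterns, scaled to an arbitrary
#' disease duration. Worsening runs toward negative values. Oscillating
#' templates have a fixed 4-year period (slight +/-10, strong +/-40); the
#' two-phase shapes switch at mid-course. Values stay within \[-100, 100\].
#'
#' @param template_id integer 1-9
#' @param duration disease duration in years (>= 1); the series has
#'   `duration + 1` yearly values
#' @param amplitude magnitude of the monotone/two-phase shapes
#' @return numeric vector of length `duration + 1`
#' @export
render_template <- function(template_id, duration, amplitude = 80) {
  if (!is_year(duration) || duration < 1) abort_ih("duration must be >= 1 year")
  id <- as.integer(template_id)
  if (is.na(id) || id < 1L || id > 9L)
    abort_ih("unknown template_id '", template_id, "'")
  t <- 0:duration
  amplitude <- clamp(amplitude, 0, 100)
  mid <- ceiling(duration / 2)
  ramp_to_mid <- pmin(t, mid) / mid
  y <- switch(id,
    -amplitude * t / duration,                       # 1 monotone worsening
    amplitude * t / duration,                        # 2 monotone improvement
    rep(0, length(t)),                               # 3 constant
    10 * sin(2 * pi * t / 4),                        # 4 slight oscillation
    40 * sin(2 * pi * t / 4),                        # 5 strong oscillation
    -amplitude * ramp_to_mid,                        # 6 worsening-then-plateau
    amplitude * ramp_to_mid,                         # 7 improvement-then-plateau
    -amplitude * (1 - abs(t - mid) / mid),           # 8 worsening-then-improvement
    amplitude * (1 - abs(t - mid) / mid))            # 9 improvement-then-worsening
  clamp(y, -100, 100)
}

default_tolerance <- function(...) {
  r <- diff(range(c(...)))
  0.01 * r
}

#' Classify yearly segments by derivative sign
#'
#' On the one-year grid the derivative is the first forward difference. A
#' difference within the tolerance band is a constant segment; above it,
#' increasing; below its negative, decreasing. The tolerance separates
#' visually-flat from analytically-increasing segments.
#'
#' @param series numeric vector, length >= 2
#' @param tolerance non-negative constancy threshold; default 1% of the
#'   series range
#' @return character vector of length `length(series) - 1` with values
#'   `"decreasing"`, `"constant"`, `"increasing"`
#' @export
classify_segments <- function(series, tolerance = NULL) {
  if (length(series) < 2L) abort_ih("series must have at least 2 points")
  if (is.null(tolerance)) tolerance <- default_tolerance(series)
  if (tolerance < 0) abort_ih("tolerance must be >= 0")
  d <- diff(series)
  ifelse(abs(d) <= tolerance, "constant",
         ifelse(d > tolerance, "increasing", "decreasing"))
}

#' Derivative-sign fit between a simulated and a reported course
#'
#' Both series are segment-classified on the shared yearly grid and the fit
#' is the percentage of segments whose classes agree, rounded to 0.1.
#'
#' @param simulated,reported numeric vectors of equal length >= 2
#' @param tolerance constancy threshold applied to both series; default 1%
#'   of their pooled range
#' @param patient_id optional identifier carried into the result
#' @return object of class `fit_result`: `patient_id`, `n_segments`,
#'   `n_matches`, `fit_percent`
#' @export
fit_percentage <- function(simulated, reported, tolerance = NULL, patient_id = NA) {
  if (length(simulated) != length(reported))
    abort_ih("simulated and reported series differ in length (",
             length(simulated), " vs ", length(reported), ")")
  if (is.null(tolerance)) tolerance <- default_tolerance(simulated, reported)
  cs <- classify_segments(simulated, tolerance)
  cr <- classify_segments(reported, tolerance)
  n_matches <- sum(cs == cr)
  n_segments <- length(cs)
  structure(
    list(patient_id = patient_id, n_segments = n_segments, n_matches = n_matches,
         fit_percent = round_half_up(100 * n_matches / n_segments, 1)),
    class = "fit_result")
}

#' Pool per-patient fits into a cohort-level fit percentage
#'
#' The default pools segments across patients (total matches over total
#' segments), so the figure reflects pattern segments, not the number of
#' patients that matched; `mode = "mean"` averages the per-patient
#' percentages instead.
#'
#' @param fits non-empty list of `fit_result`
#' @param mode `"pooled"` (default) or `"mean"`
#' @return cohort fit percentage, rounded to 0.1
#' @export
cohort_fit <- function(fits, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  if (!length(fits)) abort_ih("cohort_fit: empty fit list")
  if (mode == "pooled") {
    m <- sum(vapply(fits, function(f) f$n_matches, numeric(1)))
    s <- sum(vapply(fits, function(f) f$n_segments, numeric(1)))
    round_half_up(100 * m / s, 1)
  } else {
    round_half_up(mean(vapply(fits, function(f) f$fit_percent, numeric(1))), 1)
  }
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> patient ", x$patient_id, ": ", x$n_matches, "/", x$n_segments,
      " segments match (", x$fit_percent, "%)\n", sep = "")
  invisible(x)
}
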