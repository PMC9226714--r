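#' Signed sum of one aggregate's output over a scenario window
#'
#' Sums the aggregate's level values over all patients and all windowed
#' years. A negative sum indicates a net negative effect of the aggregate on
#' the experience of the disease.
#'
#' @param windowed_results list of (possibly windowed) `simulation_result`
#' @param aggregate aggregate name
#' @return signed sum (dimensionless)
#' @export
sum_outputs <- function(windowed_results, aggregate) {
  if (!length(windowed_results)) abort_ih("sum_outputs: no results")
  if (!aggregate %in% aggregate_names())
    abort_ih("unknown aggregate '", aggregate, "'")
  sum(vapply(windowed_results,
             function(r) sum(r$aggregates[, aggregate]), numeric(1)))
}

#' Signed sums for all twelve aggregates
#'
#' @inheritParams sum_outputs
#' @return named numeric vector of length 12
#' @export
scenario_sums <- function(windowed_results) {
  vapply(stats::setNames(nm = aggregate_names()),
         function(a) sum_outputs(windowed_results, a), numeric(1))
}

#' Absolute contribution percentages
#'
#' Each aggregate's share of the total dynamics: 100 |s_i| / sum_j |s_j|,
#' rounded half-up to one decimal for display parity with the published
#' layout.
#'
#' @param signed_sums numeric vector of per-aggregate signed sums
#' @param digits decimals to round to; `NULL` for unrounded values
#' @return percentages, same names as `signed_sums`
#' @export
contribution_percent <- function(signed_sums, digits = 1) {
  total <- sum(abs(signed_sums))
  if (total == 0) abort_ih("contribution_percent: all sums are zero")
  p <- 100 * abs(signed_sums) / total
  if (is.null(digits)) p else round_half_up(p, digits)
}

#' Build a contribution table for one scenario
#'
#' @inheritParams sum_outputs
#' @param scenario_name label stored in the table
#' @return data.frame of class `contribution_table` with columns `aggregate`,
#'   `signed_sum`, `contribution_percent`, plus attributes `scenario` and
#'   `n_patients`
#' @export
contribution_table <- function(windowed_results, scenario_name = "baseline") {
  s <- scenario_sums(windowed_results)
  out <- data.frame(aggregate = names(s), signed_sum = unname(s),
                    contribution_percent = unname(contribution_percent(s)),
                    stringsAsFactors = FALSE)
  attr(out, "scenario") <- scenario_name
  attr(out, "n_patients") <- length(windowed_results)
  class(out) <- c("contribution_table", "data.frame")
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two samples
#'
#' U is computed from rank sums with midrank ties. The p-value is exact (by
#' enumeration of the rank distribution) when there are no ties and
#' n1 * n2 <= 400, otherwise a normal approximation with tie and continuity
#' correction is used.
#'
#' @param group_a,group_b non-empty numeric vectors
#' @return list with `U` (statistic for `group_a`), `p` (two-sided), and
#'   `exact` (logical)
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    abort_ih("mann_whitney_u: empty group")
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !ties && length(group_a) * length(group_b) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = min(wt$p.value, 1), exact = exact)
}

#' Compare two scenarios aggregate by aggregate
#'
#' For each aggregate the sampling units are the per-patient windowed sums
#' (or means) of its level, compared between the two scenario result sets by
#' the Mann-Whitney test.
#'
#' @param results_a,results_b non-empty lists of windowed `simulation_result`
#' @param unit per-patient summary: `"sum"` (default) or `"mean"`
#' @param groups character vector of length 2 naming the scenarios
#' @return data.frame of class `scenario_comparison`: `aggregate`, `U`, `p`;
#'   attributes `groups` and `alpha` (0.05)
#' @export
compare_scenarios <- function(results_a, results_b, unit = c("sum", "mean"),
                              groups = c("a", "b")) {
  unit <- match.arg(unit)
  if (!length(results_a) || !length(results_b))
    abort_ih("compare_scenarios: empty scenario result set")
  fun <- if (unit == "sum") sum else mean
  per_patient <- function(results, a)
    vapply(results, function(r) fun(r$aggregates[, a]), numeric(1))
  rows <- lapply(aggregate_names(), function(a) {
    mw <- mann_whitney_u(per_patient(results_a, a), per_patient(results_b, a))
    data.frame(aggregate = a, U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  attr(out, "alpha") <- 0.05
  class(out) <- c("scenario_comparison", "data.frame")
  out
}

#' Load the reference scenario summary shipped with the package
#'
#' Per-aggregate signed simulation-output sums, published absolute
#' contribution percentages for the three scenarios, and the published
#' scenario-comparison p-values, from the original clinical study of the
#' 43-patient cohort.
#'
#' @return data.frame with one row per aggregate
#' @export
reference_scenario_sums <- function() {
  utils::read.csv(system.file("extdata", "reference_scenario_sums.csv",
                              package = "ihsim", mustWork = TRUE),
                  comment.char = "#", stringsAsFactors = FALSE)
}
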