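# shared helpers

#' Round half away from zero
#'
#' Display rounding used for percentage columns: 8.45 -> 8.5 at one decimal,
#' unlike [round()]'s round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stop() with a consistent prefix so pipeline stages can be identified
abort_ih <- function(..., class = "ihsim_error") {
  stop(errorCondition(paste0(...), class = c(class, "ihsim_error")))
}

is_year <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == trunc(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
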