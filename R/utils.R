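#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all report percentages, as
#' opposed to the round-half-even rule of [base::round()]. `0.125` rounded
#' to two decimals gives `0.13`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  z <- abs(x) * f
  # guard against values like 2.5 stored as 2.4999999999999996
  z <- trunc(z + 0.5 + sqrt(.Machine$double.eps))
  sign(x) * z / f
}

#' Percentage of a count over a denominator
#'
#' @param numerator,denominator non-negative counts; `denominator` must be
#'   positive.
#' @param decimals decimal places kept (half-up rounding).
#' @return `100 * numerator / denominator`, rounded half-up.
#' @export
#' @examples
#' percent(20013, 78311)  # 25.56
percent <- function(numerator, denominator, decimals = 2) {
  if (any(denominator <= 0)) stop("`denominator` must be > 0")
  round_half_up(100 * numerator / denominator, decimals)
}

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall; `NA` when both are zero or either
#' is `NA`.
#'
#' @param precision,recall proportions in `[0, 1]`.
#' @return the F1 score.
#' @export
f1_from_pr <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_,
         2 * precision * recall / (precision + recall))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
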