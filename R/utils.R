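# Shared internal helpers.

#' @import data.table
#' @importFrom stats rbinom rgeom rhyper rnorm rpois runif
#' @importFrom utils packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half up
#'
#' Rounds away from the banker's rounding used by [base::round()]: exact
#' halves always move away from zero, the convention used for printed
#' constituent ratios in spontaneous-report summaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.345, 2) # 2.35
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon guards against binary representation of exact halves
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Constituent ratio in percent
#'
#' `100 * count / denominator`, rounded half-up to `digits` decimals — the
#' summary statistic of the descriptive tables (category count over cohort
#' size).
#'
#' @param count category count (numeric vector).
#' @param denominator cohort size (positive scalar).
#' @param digits decimals to keep (default 2).
#' @return percentage(s) rounded half-up.
#' @export
#' @examples
#' constituent_ratio(13326, 23575) # 56.53
constituent_ratio <- function(count, denominator, digits = 2) {
  stopifnot(is.numeric(count), length(denominator) == 1L, denominator > 0)
  round_half_up(100 * count / denominator, digits)
}
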