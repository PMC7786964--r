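#' Round half-up to a fixed number of decimals
#'
#' Base \code{round()} rounds half to even; printed percentages in
#' composition and overlap reports use commercial half-up rounding
#' (e.g. 2.845 -> 2.85), so the reporting helpers go through this.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero at `digits`.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a ratio as a percentage string
#'
#' @param numerator,denominator non-negative numbers.
#' @param digits decimals kept (half-up).
#' @return character scalar such as `"63.75%"`; `"NA"` when the
#'   denominator is zero.
#' @examples
#' report_ratio(6295, 9875)
#' @export
report_ratio <- function(numerator, denominator, digits = 2) {
  if (length(denominator) != 1L || is.na(denominator) || denominator == 0)
    return("NA")
  pct <- round_half_up(100 * numerator / denominator, digits)
  paste0(formatC(pct, format = "f", digits = digits), "%")
}

# stop() with a consistent prefix for parse errors carrying a line number
parse_error <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
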