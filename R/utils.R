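#' Round for display, halves away from zero
#'
#' All model arithmetic is carried out at full double precision; rounding
#' happens only when values are displayed or tabulated. Published tables round
#' halves away from zero (e.g. -13.35 prints as -13.4), which differs from
#' [base::round()]'s round-half-to-even, so the convention is implemented
#' explicitly.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (0 for whole minutes).
#' @return Numeric vector rounded to `digits` places. `NA` stays `NA`.
#' @examples
#' round_display(c(10.05, -10.05, 7.49), 1)
#' @export
round_display <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# scalar checks used across constructors
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

euclid <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

# arc length of a polyline given as a two-column matrix
polyline_length <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) return(0)
  sum(euclid(coords[-n, 1], coords[-n, 2], coords[-1, 1], coords[-1, 2]))
}
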