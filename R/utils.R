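#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for every printed percentage in
#' the screening reports. Base [round()] rounds half to even, which disagrees
#' with published claims-report arithmetic at exact .5 boundaries.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(0.5)        # 1, where round(0.5) is 0
#' round_half_up(41.15, 1)   # 41.2
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  z <- abs(x) * p
  # nudge guards against decimal fractions stored just below .5
  trunc(z + 0.5 + sqrt(.Machine$double.eps)) * sign(x) / p
}

# stop() with a consistent condition class so callers can distinguish
# validation failures from R errors
abort_validation <- function(msg, class = "pirisk_validation_error") {
  rlang::abort(msg, class = class)
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "pirisk_format_error")
}

`%||%` <- rlang::`%||%`

# Date coercion that never errors: unparseable -> NA (callers reject those rows)
parse_date_safe <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(as.character(x), format = "%Y-%m-%d", optional = TRUE)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_format(sprintf(
      "%s: missing required column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
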