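#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish validation problems from
# missing inputs programmatically.
eds_error <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "edscores_error", "error")))
}

missing_input_error <- function(field) {
  eds_error(sprintf("missing required input: %s", field),
            "edscores_missing_input")
}

validation_error <- function(message) {
  eds_error(message, "edscores_validation_error")
}

parameter_error <- function(message) {
  eds_error(message, "edscores_parameter_error")
}

is_missing_value <- function(x) {
  is.null(x) || length(x) == 0L || all(is.na(x))
}

#' Round half-up at a given decimal resolution
#'
#' Commercial ("half-up") rounding: ties at .5 always round away from zero
#' for positive values, unlike [round()]'s round-half-even. Score band
#' tables are written over integer (or 0.1 degree) grids, so real-valued
#' vitals are snapped to that grid before lookup. A small epsilon guards
#' against binary representation error (e.g. 38.45 stored fractionally
#' below 38.45).
#'
#' @param x numeric vector.
#' @param digits decimal places to keep (0 for integers).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(120.5)      # 121
#' round_half_up(38.45, 1)   # 38.5
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (is_missing_value(x)) missing_input_error(field)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    validation_error(sprintf("%s must be a single finite number", field))
  }
  if (x < lower || x > upper) {
    validation_error(sprintf("%s = %s outside allowed range [%s, %s]",
                             field, format(x), format(lower), format(upper)))
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (is_missing_value(x)) missing_input_error(field)
  if (!(is.logical(x) && length(x) == 1L)) {
    validation_error(sprintf("%s must be a single TRUE/FALSE value", field))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
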