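#' Round half away from zero
#'
#' Presentation-layer rounding used in report tables. Base `round()` rounds
#' half to even; physiological report tables conventionally round half away
#' from zero (0.715 -> 0.72, -0.715 -> -0.72).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_flag_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_("`%s` must be finite numeric (got non-finite or non-numeric values)", name)
  }
  invisible(x)
}

# residuals of y on design X (no intercept unless a column of ones is in X);
# X may have zero columns, in which case y is returned unchanged
resid_on <- function(y, X) {
  if (is.null(X) || NCOL(X) == 0L) return(y)
  fit <- stats::lm.fit(as.matrix(X), y)
  fit$residuals
}
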