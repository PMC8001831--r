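#' Round half away from zero
#'
#' Printed clinical percentages are conventionally rounded half-up (2.65 ->
#' 2.7), unlike [base::round()] which rounds half to even.  All comparisons
#' against printed one-decimal values in this package use this convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.65, 1)  # 2.7
#' round(2.65, 1)          # 2.6
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with a stable machine-greppable code prefix, no call in message
gca_stop <- function(code, msg) {
  stop(sprintf("[%s] %s", code, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
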