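#' Round half away from zero
#'
#' Rounding convention used throughout the mixture-design arithmetic:
#' ties are rounded away from zero (so `10.505` at two decimals becomes
#' `10.51`), unlike [base::round()]'s round-half-to-even. A small relative
#' guard absorbs binary floating-point representation error so that values
#' intended to be exact ties (e.g. `21.01 / 2`) round as ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_away(10.505, 2) # 10.51
#' round_half_away(-0.025, 2) # -0.03
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, is.finite(digits))
  s <- 10^digits
  y <- abs(x) * s
  sign(x) * floor(y + 0.5 + 1e-8 * pmax(1, y)) / s
}

# Significance tiers used in all reporting: * p<0.05, ** p<0.01, *** p<0.001.
significance_tier <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = TRUE)
}

# stop() with a subclassed condition so callers can field specific failures.
stop_dntmix <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "dntmix_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
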