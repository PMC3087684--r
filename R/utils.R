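#' Round half away from zero
#'
#' Reporting rounds half away from zero (so 118.95 -> 119.0), unlike base
#' \code{round()}, which rounds half to even. Used wherever values are
#' formatted for summary tables.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (may be negative).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' roundHalfAway(0.5)    # 1
#' roundHalfAway(-0.5)   # -1
#' roundHalfAway(2.345, 2)
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# Derive a child seed from a master seed; stays below 2^31 - 1.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + offset) %% 2147483647)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
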