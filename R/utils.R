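#' Truncate trailing decimals
#'
#' Drops (rather than rounds) decimal digits beyond `digits`, i.e. rounds
#' toward zero at the given precision. Survey reports in this field often
#' truncate displayed table values instead of rounding them; the printed-table
#' emulation modes in [hpi()] and the tests use this convention when comparing
#' computed quantities against published displays.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` truncated to `digits` decimal places.
#' @examples
#' trunc_decimals(0.5899, 2) # 0.58, where round() would give 0.59
#' @export
trunc_decimals <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

# Derive a reproducible child seed (< 2^31) from a root seed and a label, so
# each stochastic input owns an independent stream and adding an input does
# not perturb the draws of the others.
child_seed <- function(root, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 1073741789L
  (bitwXor(as.integer(root %% 1073741789), as.integer(h)) %% 2147483646L) + 1L
}

assert_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    bound <- if (strict) paste(">", lower) else paste(">=", lower)
    stop(sprintf("`%s` must be a single finite number %s", name, bound),
         call. = FALSE)
  }
  invisible(x)
}

match_season <- function(season) {
  match.arg(season, SEASONS)
}
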