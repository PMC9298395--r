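`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' @keywords internal
assert_range <- function(x, name) {
  if (length(x) != 2L || any(is.na(x)) || x[1] > x[2])
    stop(sprintf("`%s` must be a nonempty range c(min, max)", name), call. = FALSE)
  invisible(as.integer(x))
}

# half-up rounding (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' @keywords internal
derive_seed <- function(seed, offset) {
  # doubles are exact here (< 2^53); result fits a 32-bit integer
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647)
}
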