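#' @keywords internal
"_PACKAGE"

# Shared small helpers. Nothing here is exported.

#' Round half away from zero
#'
#' Reporting-style rounding: 81.25 -> 81.3 at one decimal, 12.5 -> 13 at zero
#' decimals. Base R's `round()` rounds half to even and would give 81.2.
#'
#' @param x numeric vector.
#' @param places non-negative integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_away <- function(x, places = 1) {
  stopifnot(is.numeric(x), places >= 0)
  m <- 10^places
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

# %||% : default for NULL
`%||%` <- function(a, b) if (is.null(a)) b else a
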