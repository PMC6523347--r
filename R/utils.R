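# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with a stream index so that every (map, spec, k)
#' combination gets its own independent, reproducible RNG stream. The result
#' is always a positive integer below 2^31.
#'
#' @param seed master seed (single integer) or `NULL`.
#' @param index stream index (non-negative integer).
#' @return An integer seed, or `NULL` when `seed` is `NULL`.
#' @keywords internal
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime of the Lehmer generator
  s <- (abs(as.double(seed)) %% m)
  s <- (s * 48271 + as.double(index) * 30269 + 1) %% m
  # one more multiplicative round decorrelates adjacent indices
  s <- (s * 48271 + 7) %% m
  as.integer(s)
}

# Evaluate `code` under `seed` if given, else with the ambient RNG state.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

stop_usage <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_scalar_num <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}
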