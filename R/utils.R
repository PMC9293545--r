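# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
log2z <- function(x) {
  # log2 with the 0 * log2(0) := 0 convention handled by callers; here we
  # just avoid NaN warnings for x = 0 (returns -Inf as log2 does).
  ifelse(x > 0, log2(x), -Inf)
}

# Deterministically derive a child seed from a parent seed and an index.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647L + 999983 * (as.double(i) %% 2147483L)) %% 2147483647L)
}

# Run expr with a local RNG state so library calls never clobber the
# caller's random stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
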