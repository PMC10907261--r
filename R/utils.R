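# internal helpers shared across modules

# Clamp ratings to the 0-100 visual-analogue scale.
clip_rating <- function(x, lo = 0, hi = 100) pmin(hi, pmax(lo, x))

# Deterministic child seed derived from a master seed and a stream index.
# Kept strictly inside [1, 2^31 - 2] so set.seed() never overflows.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                as.double(index) * 9973) %% 2147483645 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_positive_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_rating <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100)) {
    stop(sprintf("'%s' must lie in [0, 100]", name), call. = FALSE)
  }
  invisible(x)
}

assert_unit_interval <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
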