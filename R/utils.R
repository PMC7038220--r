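`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

assert_count <- function(x, name, min = 1L) {
  if (!is_count(x, min)) stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stopf("`%s` must be a single number in [%s, %s]", name, format(lo), format(hi))
  as.numeric(x)
}

# Deterministic child seed (kept well under 2^31) for deriving independent
# RNG streams from one user-facing seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483562)
}
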