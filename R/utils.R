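# Internal helpers shared across modules.

# Derive a 32-bit-safe child seed from a base seed and an index.
# Deterministic, collision-poor for the index ranges used here (PSA
# iterations, bootstrap replicates, chain ids).
child_seed <- function(seed, index, stream = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 16807 + as.double(stream) * 69621) %% 2147483647
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Discount factor for end-of-cycle accrual: cycle t (1-based) is divided
# by (1 + rate)^t.
discount_factors <- function(n_cycles, rate) {
  if (rate < 0) stopf("discount rate must be non-negative, got %g", rate)
  (1 + rate)^-(seq_len(n_cycles))
}
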