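# Internal helpers shared across modules.

# Evaluate `code` under `seed` if non-NULL, restoring the RNG afterwards;
# with seed = NULL the current RNG stream is used (callers embedded in a
# larger seeded computation rely on this).
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Round half away from zero (base round() is round-half-even, which
# would turn 11322.5 into 11322 instead of the 11323 the balancing rule
# requires).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
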