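# internal helpers shared across modules

# clip values into [lo, hi] componentwise
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a child seed from a run seed; kept below 2^31
childSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2017L + as.integer(offset) * 7919L
}

# round half up at `digits` decimals (display convention for percent metrics;
# round() rounds half to even, which disagrees with printed tables at .5)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# sign-preserving epsilon-guarded ratio: denominators of magnitude < eps are
# pushed to +-eps so ratios of near-achromatic channel means stay finite
guardedRatio <- function(x, y, eps = 1e-9) {
  s <- ifelse(y < 0, -1, 1)
  x / (s * pmax(abs(y), eps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
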