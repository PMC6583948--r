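# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All user-facing randomized
# operations funnel through this so a single integer seed makes any
# pipeline stage reproducible without clobbering the session RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive independent per-replicate substream seeds from one master seed, so
# resampling curves are reproducible replicate-by-replicate.
substreamSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}

# Percentile CI endpoints as order statistics (type 7 would interpolate;
# the classical percentile bootstrap uses empirical quantiles, type 1).
percentileCI <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(c(NA_real_, NA_real_))
  alpha <- (1 - level) / 2
  unname(quantile(x, probs = c(alpha, 1 - alpha), type = 1, names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
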