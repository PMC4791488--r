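## Seed plumbing.  Every stochastic function takes an explicit integer seed and
## evaluates under a locally-set RNG state, restoring the caller's state on
## exit.  Sub-streams (per study size, per replicate, per bootstrap stage) use
## deterministic derived seeds so that grids and nested procedures are
## reproducible without sharing one global stream.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Mix a base seed with stream indices into a positive integer < 2^31 - 1.
## Two multiplicative rounds (Lehmer-style constants) in double precision;
## exact below 2^53 so the arithmetic is reproducible across platforms.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    x <- (x * 48271 + as.numeric(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(x) + 1L
}
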