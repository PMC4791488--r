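## Independent oracles and tiny engines used across the test files.

## Grid-search oracle for the non-centrality MLE: coarse scan of the summed
## log-density over [0, upper], then a dense refinement (step 1e-4) around the
## coarse maximiser; ties break toward smaller lambda.
grid_oracle_lambda <- function(values, df, upper = 50) {
  obj <- function(l) sum(dncx2(values, df, l, log = TRUE))
  coarse <- seq(0, upper, by = 0.01)
  oc <- vapply(coarse, obj, numeric(1))
  l0 <- coarse[which.max(oc)]  # which.max returns the first (smallest) tie
  fine <- seq(max(0, l0 - 0.02), min(upper, l0 + 0.02), by = 1e-4)
  of <- vapply(fine, obj, numeric(1))
  fine[which.max(of)]
}

## Bisection oracle: the non-centrality parameter that yields a target power
## for a df-degree chi-square test at level alpha.
bisect_lambda_for_power <- function(target, df = 1, alpha = 0.05,
                                    lo = 0, hi = 100) {
  q <- qchisq(1 - alpha, df)
  f <- function(l) pchisq(q, df, ncp = l, lower.tail = FALSE) - target
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

## Engine stubs.
constant_engine <- function(value, df = 1) {
  structure(function(n, seed) value, df = df, label = "constant",
            batch = function(n, s, seed) rep(value, s))
}

central_chisq_engine <- function(df = 1) {
  structure(function(n, seed) ppestim:::with_seed(seed, rchisq(1, df)),
            df = df, label = "central-chisq",
            batch = function(n, s, seed)
              ppestim:::with_seed(seed, rchisq(s, df)))
}

## An engine whose replicates fail with a fixed probability.
flaky_engine <- function(fail_prob, value = 10, df = 1) {
  structure(function(n, seed) ppestim:::with_seed(seed, {
    if (runif(1) < fail_prob) stop("replicate failed") else value
  }), df = df, label = "flaky")
}
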