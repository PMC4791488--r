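## Evaluation harness: repeated paired runs of the Monte Carlo and parametric
## power estimators against a high-replicate Monte Carlo reference, summarised
## by relative bias, standard deviation and range; plus the bootstrap coverage
## study.

.reference_cache <- new.env(parent = emptyenv())

#' Reference power by high-replicate Monte Carlo
#'
#' Runs the Monte Carlo power estimator with a large number of replicates
#' (default 10,000) at one study size; the result serves as the reference
#' value in bias/precision/coverage studies.  Results are cached in-session
#' under a key formed from the engine label, size, replicate count and seed.
#'
#' @param engine a statistic engine (see [sse_engine()]).
#' @param n study size.
#' @param s_reference Monte Carlo replicates.
#' @param seed integer seed.
#' @param alpha significance level.
#' @return the reference power (scalar in \[0, 1\]).
#' @export
reference_power <- function(engine, n, s_reference = 10000, seed = 1,
                            alpha = 0.05) {
  key <- paste(attr(engine, "label") %||% "engine", n, s_reference, seed,
               alpha, sep = "|")
  if (!is.null(.reference_cache[[key]])) return(.reference_cache[[key]])
  stats <- engine_statistics(engine, n, s_reference, derive_seed(seed, 777))
  res <- mcpe(suppressWarnings(
    statistic_sample(stats, attr(engine, "df") %||% 1L)), alpha = alpha)
  .reference_cache[[key]] <- res$power
  res$power
}

#' Summarise repeated power estimates against a reference
#'
#' Computes the three performance measures used throughout the evaluation, on
#' the percent scale:
#' relative bias `100 * (mean - reference) / reference`, standard deviation
#' `100 * sd(estimates)` (divisor L - 1) and range `100 * (max - min)`.
#'
#' @param estimates numeric vector of power estimates in \[0, 1\] (length >= 2).
#' @param reference reference power in (0, 1).
#' @return one-row data frame with `rel_bias_pct`, `sd_pct`, `range_pct`,
#'   `reference_power`, `n_runs`.
#' @export
#' @examples
#' summarize_runs(c(0.7, 0.8, 0.9), reference = 0.8)
summarize_runs <- function(estimates, reference) {
  stopifnot(is.numeric(estimates), reference > 0, reference < 1)
  if (length(estimates) < 2)
    stop("at least two estimates are needed (the SD is undefined for one)")
  data.frame(rel_bias_pct = 100 * (mean(estimates) - reference) / reference,
             sd_pct = 100 * stats::sd(estimates),
             range_pct = 100 * (max(estimates) - min(estimates)),
             reference_power = reference,
             n_runs = length(estimates))
}

#' Compare the Monte Carlo and parametric power estimators
#'
#' For each Monte Carlo sample size in `s_values`, runs `l_runs` independent
#' studies of `s` statistics at study size `n_star`.  Both estimators see the
#' same statistic pool within a run (a paired design, which reduces the noise
#' of the comparison without changing either marginal summary): the Monte
#' Carlo estimate is the rejection fraction, the parametric estimate comes
#' from the fitted non-centrality parameter.  Summaries are computed against
#' a common high-replicate reference.
#'
#' @param engine a statistic engine.
#' @param n_star study size of the comparison.
#' @param s_values Monte Carlo sample sizes per run.
#' @param l_runs number of repeated runs L per sample size.
#' @param seed integer seed.
#' @param reference reference power; computed via [reference_power()] with
#'   `s_reference` replicates when `NULL`.
#' @param s_reference replicates for the reference run.
#' @param alpha significance level.
#' @return data frame with one row per (method, s): columns `method`
#'   (`"MCPE"`/`"PPE"`), `s`, and the [summarize_runs()] measures.
#' @export
run_method_comparison <- function(engine, n_star, s_values = c(100, 200, 400),
                                  l_runs = 1000, seed = 1, reference = NULL,
                                  s_reference = 10000, alpha = 0.05) {
  df <- attr(engine, "df") %||% 1L
  if (is.null(reference))
    reference <- reference_power(engine, n_star, s_reference, seed, alpha)
  crit <- critical_value(df, alpha)
  out <- lapply(seq_along(s_values), function(si) {
    s <- s_values[si]
    stats <- engine_statistics(engine, n_star, l_runs * s,
                               derive_seed(seed, si))
    X <- matrix(stats, nrow = l_runs, byrow = TRUE)
    ok <- is.finite(X)
    if (!all(ok)) {
      ## failed replicates leave the MCPE denominator and are clamped out of
      ## the PPE sample by row-wise refitting below
      mc <- rowSums(X > crit, na.rm = TRUE) / rowSums(ok)
      lam <- vapply(seq_len(l_runs), function(l) {
        v <- pmax(X[l, ok[l, ]], 0)
        fit_lambda(v, df)$lambda
      }, numeric(1))
    } else {
      mc <- rowMeans(X > crit)
      lam <- fit_lambda_batch(pmax(X, 0), df)
    }
    pp <- power_from_lambda(lam, df, alpha)
    rbind(cbind(method = "MCPE", s = s, summarize_runs(mc, reference)),
          cbind(method = "PPE", s = s, summarize_runs(pp, reference)))
  })
  structure(do.call(rbind, out), reference = reference,
            class = c("ppe_comparison", "data.frame"))
}

#' Coverage of the bootstrap power confidence interval
#'
#' Repeats the full estimate-then-bootstrap pipeline `l_runs` times: draw
#' `s_p` statistics at study size `n_star`, fit the non-centrality parameter,
#' build the bootstrap confidence interval for the power at `n_star`, and
#' record whether it contains the reference power.  Returns the fraction of
#' covering intervals.
#'
#' @inheritParams run_method_comparison
#' @param s_p Monte Carlo sample size per run.
#' @param b bootstrap sets per run.
#' @param level confidence level.
#' @return coverage fraction in \[0, 1\], with attributes `l_runs` and
#'   `reference`.
#' @export
run_coverage_study <- function(engine, n_star, s_p = 400, b = 1000,
                               l_runs = 1000, seed = 1, reference = NULL,
                               s_reference = 10000, alpha = 0.05,
                               level = 0.95) {
  df <- attr(engine, "df") %||% 1L
  if (is.null(reference))
    reference <- reference_power(engine, n_star, s_reference, seed, alpha)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  covered <- vapply(seq_len(l_runs), function(l) {
    stats <- engine_statistics(engine, n_star, s_p, derive_seed(seed, 1, l))
    v <- pmax(stats[is.finite(stats)], 0)
    lam <- fit_lambda(v, df)$lambda
    X <- with_seed(derive_seed(seed, 2, l),
                   matrix(stats::rchisq(b * s_p, df, ncp = lam), nrow = b))
    lam_b <- fit_lambda_batch(X, df)
    ci <- stats::quantile(lam_b, probs, type = 7)
    p <- power_from_lambda(ci, df, alpha)
    reference >= p[1] && reference <= p[2]
  }, logical(1))
  structure(mean(covered), l_runs = l_runs, reference = reference)
}
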