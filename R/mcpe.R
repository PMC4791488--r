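#' Monte Carlo power estimation (MCPE)
#'
#' The classical reference estimator: the power is the fraction of simulated
#' and re-estimated replicates whose test statistic exceeds the central
#' chi-square critical value.  Rejection uses the strict inequality
#' `t > critical value`; ties do not reject (the reference distribution is
#' continuous).
#'
#' @param x numeric vector of test statistics, or a [statistic_sample()].
#' @param df degrees of freedom of the test.
#' @param alpha significance level in (0, 1).
#' @param negative_policy see [statistic_sample()].
#' @return object of class `"mcpe"`: list with `power` (the exact fraction
#'   `n_rejected / n_total`), `n_rejected`, `n_total`, `critical_value`.
#' @export
#' @examples
#' mcpe(c(1, 2, 5, 10), df = 1)  # two of four exceed 3.84 -> power 0.5
mcpe <- function(x, df = 1, alpha = 0.05, negative_policy = "clamp") {
  sample <- as_statistic_sample(x, df, negative_policy)
  stopifnot(alpha > 0, alpha < 1)
  crit <- critical_value(sample$df, alpha)
  n_rej <- sum(sample$values > crit)
  n_tot <- length(sample$values)
  structure(list(power = n_rej / n_tot, n_rejected = as.integer(n_rej),
                 n_total = as.integer(n_tot), critical_value = crit,
                 df = sample$df, alpha = alpha),
            class = "mcpe")
}

#' @export
print.mcpe <- function(x, digits = 4, ...) {
  cat("Monte Carlo power estimate (MCPE)\n")
  cat("  power:", format(x$power, digits = digits),
      sprintf("(%d / %d rejections, critical value %.4f)\n",
              x$n_rejected, x$n_total, x$critical_value))
  invisible(x)
}

#' Monte Carlo power curve over a grid of study sizes
#'
#' Runs the MCPE algorithm at each study size of a grid: `s_m` statistics are
#' generated per size through a simulate-and-fit engine and summarised into a
#' rejection-rate power estimate.  Replicate streams are seeded independently
#' per size and replicate from `seed`, so the curve is reproducible and
#' engines may evaluate replicates in any order.
#'
#' Engine protocol: `engine(n, seed)` returns one test statistic for a study
#' of `n` subjects (`NA` for a failed replicate).  Engines may carry a
#' `"batch"` attribute, `function(n, s, seed) -> numeric(s)`, used when
#' present to generate all replicates of a size in one call (see
#' [sse_engine()], [ncx2_engine()]).  Failed replicates are excluded from the
#' denominator and counted; a size where more than 20% of replicates fail is
#' flagged and a warning is raised.
#'
#' @param engine simulate-and-fit callable as described above.
#' @param sizes strictly increasing integer vector of study sizes.
#' @param s_m Monte Carlo replicates per size.
#' @param seed integer seed.
#' @param df degrees of freedom (defaults to the engine's `"df"` attribute).
#' @param alpha significance level.
#' @param negative_policy see [statistic_sample()].
#' @return data frame of class `"mcpe_curve"` with columns `n`, `power`,
#'   `n_rejected`, `n_total`, `n_failed`, `flagged`.
#' @export
mcpe_power_curve <- function(engine, sizes, s_m, seed, df = NULL,
                             alpha = 0.05, negative_policy = "clamp") {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1, all(sizes >= 1),
            !is.unsorted(sizes, strictly = TRUE), s_m >= 1)
  if (is.null(df)) df <- attr(engine, "df")
  if (is.null(df)) stop("supply 'df' (the engine carries no \"df\" attribute)")
  rows <- lapply(seq_along(sizes), function(k) {
    stats <- engine_statistics(engine, sizes[k], s_m, derive_seed(seed, k))
    n_failed <- sum(!is.finite(stats))
    if (n_failed == s_m)
      stop("all ", s_m, " replicates failed at study size ", sizes[k])
    sam <- suppressWarnings(
      statistic_sample(stats, df, negative_policy = negative_policy))
    res <- mcpe(sam, alpha = alpha)
    flagged <- n_failed > 0.2 * s_m
    if (flagged)
      warning(sprintf("study size %d: %d of %d replicates failed (> 20%%)",
                      sizes[k], n_failed, s_m))
    data.frame(n = sizes[k], power = res$power, n_rejected = res$n_rejected,
               n_total = res$n_total, n_failed = n_failed, flagged = flagged)
  })
  structure(do.call(rbind, rows), alpha = alpha, df = df, s_m = s_m,
            class = c("mcpe_curve", "data.frame"))
}

## Generate s statistics at size n from an engine, using its batch capability
## when present, otherwise one seeded call per replicate.
engine_statistics <- function(engine, n, s, seed) {
  batch <- attr(engine, "batch")
  if (is.function(batch)) return(batch(n, s, seed))
  vapply(seq_len(s), function(r) {
    val <- tryCatch(engine(n, derive_seed(seed, r)), error = function(e) NA_real_)
    if (length(val) != 1L) NA_real_ else as.numeric(val)
  }, numeric(1))
}
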