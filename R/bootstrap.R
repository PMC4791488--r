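#' Parametric bootstrap for Monte Carlo uncertainty of a PPE fit
#'
#' Quantifies the Monte Carlo noise in the estimated non-centrality parameter
#' (and hence in the power estimates) that stems from the finite number of
#' simulation-estimation replicates.  `B` synthetic statistic sets of size
#' `s_p` are drawn from the fitted non-central chi-square distribution, the
#' non-centrality parameter is re-estimated on each, and the 2.5th/97.5th
#' percentiles (for `level = 0.95`) of the re-estimates are mapped to power
#' bounds at each requested study size via linear scaling and the non-central
#' chi-square survival function.
#'
#' @param fit a converged `"ppe"` fit.
#' @param B number of bootstrap sets (>= 100).
#' @param s_p statistics per set (defaults to the fitted sample's size; >= 2).
#' @param sizes study sizes at which power bounds are wanted.
#' @param seed integer seed.
#' @param level confidence level.
#' @return object of class `"ppe_bootstrap"`: list with `b` (sets retained),
#'   `lambda_draws`, `lambda_ci`, `power_ci_by_size` (matrix with columns
#'   `low`, `high`, one row per size), `n_failed`.
#' @export
#' @examples
#' set.seed(1)
#' fit <- ppe(rchisq(400, 1, ncp = 7.85), df = 1, n_ref = 200)
#' bs <- ppe_bootstrap(fit, B = 200, sizes = c(100, 200), seed = 42)
#' bs$power_ci_by_size
ppe_bootstrap <- function(fit, B = 1000, s_p = NULL, sizes = NULL,
                          seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "ppe"))
  if (!fit$converged) stop("the PPE fit did not converge; no bootstrap run")
  if (is.null(s_p)) s_p <- length(fit$sample$values)
  stopifnot(s_p >= 2, B >= 100, level > 0, level < 1)
  if (is.null(sizes)) sizes <- fit$n_ref
  if (is.null(sizes)) stop("supply 'sizes' or refit with 'n_ref'")
  n_ref <- fit$n_ref %||% sizes[1]
  X <- with_seed(seed, matrix(stats::rchisq(B * s_p, fit$df, ncp = fit$lambda),
                              nrow = B))
  lam_b <- fit_lambda_batch(X, fit$df)
  bad <- !is.finite(lam_b)
  if (any(bad)) {
    if (mean(bad) > 0.1)
      stop(sprintf("%d of %d bootstrap re-estimations failed (> 10%%)",
                   sum(bad), B))
    lam_b <- lam_b[!bad]
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  lam_ci <- unname(stats::quantile(lam_b, probs, type = 7))
  power_ci <- t(vapply(sizes, function(nk) {
    power_from_lambda(scale_lambda(lam_ci, n_ref, nk), fit$df, fit$alpha)
  }, numeric(2)))
  dimnames(power_ci) <- list(as.character(sizes), c("low", "high"))
  structure(list(b = length(lam_b), lambda_draws = lam_b, lambda_ci = lam_ci,
                 power_ci_by_size = power_ci, n_failed = sum(bad),
                 level = level, s_p = as.integer(s_p), n_ref = n_ref),
            class = "ppe_bootstrap")
}

#' @export
print.ppe_bootstrap <- function(x, digits = 4, ...) {
  cat("PPE parametric bootstrap:", x$b, "sets of", x$s_p, "statistics\n")
  cat(sprintf("  lambda %.0f%% CI: [%s, %s]\n", 100 * x$level,
              format(x$lambda_ci[1], digits = digits),
              format(x$lambda_ci[2], digits = digits)))
  print(round(x$power_ci_by_size, digits))
  invisible(x)
}

#' Bootstrap-based diagnostic for the non-central chi-square assumption
#'
#' The PPE power estimate is only trustworthy when the test statistics really
#' follow a non-central chi-square distribution.  This diagnostic overlays the
#' empirical CDF of the observed statistics with a confidence band of
#' non-central chi-square CDFs derived from the parametric bootstrap: the
#' re-estimated non-centrality parameters falling inside their own central
#' `level` percentile range are retained (`retain = "ci"`) and the band is the
#' pointwise envelope (min/max, `band = "envelope"`) of their CDFs, or the
#' pointwise percentile band of the CDF values (`band = "percentile"`).
#' Boundary-constrained hypotheses (mass of the statistic at zero), biased
#' estimators or model misspecification push the empirical CDF outside the
#' band.
#'
#' The band quantifies only the Monte Carlo uncertainty of the estimated
#' non-centrality parameter; the empirical CDF additionally carries its own
#' binomial sampling noise, of comparable magnitude, so a strict pointwise
#' comparison would flag correctly specified samples routinely.  A statistic
#' therefore counts as *outside* only when its empirical CDF step lies beyond
#' the band by more than a sampling margin.  The default margin
#' (`ecdf_margin = "adaptive"`) is three pointwise binomial standard
#' deviations at the nearest band edge, `3 sqrt(F (1 - F) / n)`: it shrinks
#' to zero in the tails, where any appreciable empirical mass (the signature
#' of a boundary-constrained hypothesis, a point mass of statistics at zero)
#' is decisive evidence, and roughly matches a uniform
#' Dvoretzky-Kiefer-Wolfowitz band in the middle of the distribution.
#' `ecdf_margin = "dkw"` uses the uniform DKW margin
#' `sqrt(log(2 / (1 - level)) / (2 n))`; `"none"` compares strictly
#' pointwise.  The fraction of outside statistics is reported; a fraction
#' above 0.05 raises a warning (the diagnostic is known to be sensitive, so
#' it is not an error).
#'
#' @param fit a converged `"ppe"` fit (carries the observed sample).
#' @param B number of bootstrap sets.
#' @param seed integer seed.
#' @param band band construction, `"envelope"` or `"percentile"`.
#' @param retain `"ci"` (default) restricts to re-estimates inside the central
#'   `level` range, `"all"` uses every bootstrap re-estimate.
#' @param level confidence level.
#' @param ecdf_margin sampling allowance for the empirical CDF before a
#'   statistic counts as outside: `"adaptive"` (default, pointwise binomial),
#'   `"dkw"` (uniform), or `"none"` (strict).
#' @param grid_length number of grid points spanning `[0, 1.2 * max(t)]`.
#' @return object of class `"ppe_diagnostic"`: list with `t_grid`, `band_low`,
#'   `band_high` (CDF bands on the grid), `statistics`, `ecdf` (empirical CDF
#'   at the observed statistics), `outside_fraction`, `flagged`.
#' @export
ppe_diagnostic <- function(fit, B = 1000, seed = NULL,
                           band = c("envelope", "percentile"),
                           retain = c("ci", "all"), level = 0.95,
                           ecdf_margin = c("adaptive", "dkw", "none"),
                           grid_length = 512) {
  band <- match.arg(band)
  retain <- match.arg(retain)
  ecdf_margin <- match.arg(ecdf_margin)
  stopifnot(inherits(fit, "ppe"))
  bs <- ppe_bootstrap(fit, B = B, sizes = fit$n_ref %||% 1L, seed = seed,
                      level = level)
  lam_b <- bs$lambda_draws
  if (retain == "ci") {
    keep <- lam_b >= bs$lambda_ci[1] & lam_b <= bs$lambda_ci[2]
    lam_b <- lam_b[keep]
  }
  t_obs <- sort(fit$sample$values)
  t_max <- max(t_obs) * 1.2
  t_grid <- seq(0, t_max, length.out = grid_length)
  grid_band <- ncx2_cdf_band(lam_b, fit$df, t_grid, band, level)
  obs_band <- ncx2_cdf_band(lam_b, fit$df, t_obs, band, level)
  n <- length(t_obs)
  ecdf_vals <- stats::ecdf(t_obs)(t_obs)
  ecdf_lower <- ecdf_vals - 1 / n  # left limit of the ECDF step
  if (ecdf_margin == "adaptive") {
    ## + 2/n: discreteness allowance, so a couple of clamped-to-zero
    ## statistics (optimiser noise artifacts) do not register as mass
    eps_hi <- 3 * sqrt(obs_band$high * (1 - obs_band$high) / n) + 2 / n
    eps_lo <- 3 * sqrt(obs_band$low * (1 - obs_band$low) / n) + 2 / n
  } else if (ecdf_margin == "dkw") {
    eps_hi <- eps_lo <- sqrt(log(2 / (1 - level)) / (2 * n))
  } else {
    eps_hi <- eps_lo <- 0
  }
  outside <- (ecdf_lower - eps_hi) > obs_band$high |
    (ecdf_vals + eps_lo) < obs_band$low
  outside_fraction <- mean(outside)
  flagged <- outside_fraction > 0.05
  if (flagged)
    warning(sprintf(paste0("empirical CDF outside the bootstrap band for ",
                           "%.1f%% of statistics; the non-central chi-square ",
                           "assumption may be violated"),
                    100 * outside_fraction))
  structure(list(t_grid = t_grid, band_low = grid_band$low,
                 band_high = grid_band$high, statistics = t_obs,
                 ecdf = ecdf_vals, outside_fraction = outside_fraction,
                 flagged = flagged, b_retained = length(lam_b),
                 band = band, retain = retain, level = level),
            class = "ppe_diagnostic")
}

## Pointwise CDF band over a set of non-centrality draws, evaluated at tt:
## envelope (min/max) or central percentile band of the CDF values.
ncx2_cdf_band <- function(lam_draws, df, tt, band = "envelope", level = 0.95) {
  cdf <- matrix(vapply(lam_draws, function(l) stats::pchisq(tt, df, ncp = l),
                       numeric(length(tt))), nrow = length(tt))
  if (band == "envelope") {
    list(low = apply(cdf, 1L, min), high = apply(cdf, 1L, max))
  } else {
    qs <- apply(cdf, 1L, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2), type = 7)
    list(low = qs[1, ], high = qs[2, ])
  }
}

#' @export
print.ppe_diagnostic <- function(x, ...) {
  cat("PPE distributional diagnostic (", x$band, " band, ",
      x$b_retained, " retained bootstrap draws)\n", sep = "")
  cat(sprintf("  fraction of statistics outside the band: %.3f%s\n",
              x$outside_fraction,
              if (x$flagged) "  ** assumption suspect **" else ""))
  invisible(x)
}

#' @export
plot.ppe_diagnostic <- function(x, xlab = "test statistic",
                                ylab = "cumulative probability", ...) {
  graphics::plot(x$t_grid, x$band_high, type = "n", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$t_grid, rev(x$t_grid)),
                    c(x$band_low, rev(x$band_high)),
                    col = "grey85", border = NA)
  graphics::lines(stats::stepfun(x$statistics, c(0, x$ecdf)), do.points = FALSE)
  invisible(x)
}
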