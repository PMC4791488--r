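#' Fit the parametric power estimation (PPE) model to a sample of statistics
#'
#' Estimates the non-centrality parameter lambda of the non-central chi-square
#' distribution by maximum likelihood from a sample of test statistics
#' obtained under the alternative hypothesis,
#' \deqn{\hat\lambda = \arg\max_{\lambda \ge 0} \sum_s \log f_{\chi^2}(t_s; k, \lambda),}
#' and converts it to a power estimate via the non-central chi-square survival
#' function.  Because lambda is proportional to the number of subjects when a
#' reference design is replicated, a fit at one study size yields the whole
#' power-versus-study-size curve (see [predict.ppe()]).
#'
#' The score of the objective at `lambda = 0` equals `sum(t - k) / (2k)`; when
#' it is nonpositive, the boundary `lambda = 0` is the exact MLE and is
#' returned directly.  Otherwise a golden-section/parabolic search with
#' tolerance 1e-8 is used on `[0, max(t) + 10 k]`.
#'
#' @param x numeric vector of test statistics, or a [statistic_sample()].
#' @param df degrees of freedom of the test (ignored when `x` carries its own).
#' @param alpha significance level in (0, 1).
#' @param n_ref study size (number of subjects) at which the statistics were
#'   generated; required for power curves across sizes.
#' @param negative_policy how to treat negative statistics, see
#'   [statistic_sample()].
#' @return an object of class `"ppe"` with components `lambda`, `loglik`,
#'   `at_boundary`, `converged`, `sample`, `df`, `alpha`, `n_ref`.
#' @references The estimator and its study-size scaling follow the parametric
#'   power estimation approach for mixed-effects models.
#' @export
#' @examples
#' set.seed(1)
#' t_stats <- rchisq(400, df = 1, ncp = 7.85)
#' fit <- ppe(t_stats, df = 1, n_ref = 200)
#' fit
#' predict(fit, n = c(100, 200, 400))
ppe <- function(x, df = 1, alpha = 0.05, n_ref = NULL,
                negative_policy = "clamp") {
  sample <- as_statistic_sample(x, df, negative_policy)
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(n_ref)) stopifnot(n_ref >= 1)
  if (length(sample$values) == 1L)
    warning("non-centrality estimated from a single statistic; ",
            "the power estimate will be very imprecise")
  fit <- fit_lambda(sample$values, sample$df)
  structure(
    list(lambda = fit$lambda, loglik = fit$loglik,
         at_boundary = fit$at_boundary, converged = fit$converged,
         sample = sample, df = sample$df, alpha = alpha,
         n_ref = if (is.null(n_ref)) NULL else as.integer(n_ref),
         call = match.call()),
    class = "ppe")
}

#' @export
print.ppe <- function(x, digits = 4, ...) {
  cat("Parametric power estimation (PPE) fit\n")
  cat("  statistics:", length(x$sample$values), " df:", x$df,
      " alpha:", x$alpha, "\n")
  cat("  lambda: ", format(x$lambda, digits = digits),
      if (x$at_boundary) " (boundary: sample mean <= df)" else "", "\n", sep = "")
  p <- power_from_lambda(x$lambda, x$df, x$alpha)
  if (!is.null(x$n_ref)) {
    cat("  power at reference size N =", x$n_ref, ":",
        format(p, digits = digits), "\n")
  } else {
    cat("  power at the sampled study size:", format(p, digits = digits), "\n")
  }
  invisible(x)
}

#' @export
coef.ppe <- function(object, ...) c(lambda = object$lambda)

#' @export
logLik.ppe <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = length(object$sample$values),
            class = "logLik")
}

#' Summary of a PPE fit
#'
#' Adds a standard error for the estimated non-centrality parameter from the
#' observed information (numerical second derivative of the objective at the
#' optimum; `NA` at the boundary `lambda = 0`).
#'
#' @param object a `"ppe"` fit.
#' @param ... unused.
#' @export
summary.ppe <- function(object, ...) {
  se <- NA_real_
  if (!object$at_boundary) {
    h <- max(1e-4, 1e-5 * object$lambda)
    l <- object$lambda
    d2 <- (ncx2_loglik(l + h, object$sample$values, object$df) -
           2 * object$loglik +
           ncx2_loglik(l - h, object$sample$values, object$df)) / h^2
    if (is.finite(d2) && d2 < 0) se <- sqrt(-1 / d2)
  }
  out <- object
  out$se_lambda <- se
  out$power <- power_from_lambda(object$lambda, object$df, object$alpha)
  class(out) <- c("summary.ppe", "ppe")
  out
}

#' @export
print.summary.ppe <- function(x, digits = 4, ...) {
  print.ppe(x, digits = digits, ...)
  cat("  se(lambda):", format(x$se_lambda, digits = digits),
      " log-likelihood:", format(x$loglik, digits = digits), "\n")
  cat("  preprocessing: raw", x$sample$n_raw, "/ dropped", x$sample$n_dropped,
      "/ clamped", x$sample$n_clamped, "\n")
  invisible(x)
}

#' Power curve from a PPE fit
#'
#' Scales the fitted non-centrality parameter linearly from the reference
#' study size to each requested size and converts it to power.  Optionally
#' adds parametric-bootstrap confidence bands (see [ppe_bootstrap()]).
#'
#' @param object a `"ppe"` fit with a reference size `n_ref`.
#' @param n integer vector of study sizes, strictly increasing.
#' @param interval `"none"` or `"bootstrap"`.
#' @param level confidence level for the bootstrap interval.
#' @param B number of bootstrap sets.
#' @param seed integer seed for the bootstrap.
#' @param ... unused.
#' @return a data frame of class `"ppe_curve"` with columns `n`, `lambda`,
#'   `power` and, when requested, `ci_low`, `ci_high`; attributes `n_ref`,
#'   `lambda_ref`, `alpha`, `df`.
#' @export
predict.ppe <- function(object, n, interval = c("none", "bootstrap"),
                        level = 0.95, B = 1000, seed = NULL, ...) {
  interval <- match.arg(interval)
  if (is.null(object$n_ref))
    stop("the PPE fit has no reference study size; refit with 'n_ref'")
  n <- as.integer(n)
  if (length(n) == 0L || any(n < 1) || is.unsorted(n, strictly = TRUE))
    stop("'n' must be a non-empty, strictly increasing vector of positive sizes")
  lam <- scale_lambda(object$lambda, object$n_ref, n)
  out <- data.frame(n = n, lambda = lam,
                    power = power_from_lambda(lam, object$df, object$alpha))
  if (interval == "bootstrap") {
    bs <- ppe_bootstrap(object, B = B, sizes = n, seed = seed, level = level)
    out$ci_low <- bs$power_ci_by_size[, "low"]
    out$ci_high <- bs$power_ci_by_size[, "high"]
  }
  structure(out, n_ref = object$n_ref, lambda_ref = object$lambda,
            alpha = object$alpha, df = object$df,
            class = c("ppe_curve", "data.frame"))
}

#' One-call PPE power curve
#'
#' Convenience wrapper around [ppe()] and [predict.ppe()]: fits the
#' non-centrality parameter to the statistics and evaluates the power curve on
#' a study-size grid.  At `n = n_ref` the curve equals the single-size PPE
#' power estimate exactly.
#'
#' @inheritParams ppe
#' @param sizes strictly increasing integer vector of study sizes.
#' @param ... passed on to [predict.ppe()] (e.g. `interval`, `B`, `seed`).
#' @return a `"ppe_curve"` data frame.
#' @export
ppe_power_curve <- function(x, df = 1, alpha = 0.05, n_ref, sizes, ...) {
  fit <- ppe(x, df = df, alpha = alpha, n_ref = n_ref)
  predict(fit, n = sizes, ...)
}

#' @export
plot.ppe_curve <- function(x, ylim = c(0, 1), type = "b", pch = 16,
                           xlab = "study size (subjects)", ylab = "power", ...) {
  graphics::plot(x$n, x$power, type = type, pch = pch, ylim = ylim,
                 xlab = xlab, ylab = ylab, ...)
  if (!is.null(x$ci_low)) {
    graphics::lines(x$n, x$ci_low, lty = 2)
    graphics::lines(x$n, x$ci_high, lty = 2)
  }
  graphics::abline(h = attr(x, "alpha"), col = "grey", lty = 3)
  invisible(x)
}

#' @export
plot.ppe <- function(x, n = NULL, ...) {
  if (is.null(n)) {
    if (is.null(x$n_ref)) stop("supply 'n' or refit with 'n_ref'")
    n <- even_size(x$n_ref * c(0.25, 0.5, 0.75, 1, 1.25))
  }
  plot(predict(x, n = n), ...)
}

#' Simulate statistic sets from a fitted PPE model
#'
#' Draws parametric-bootstrap sets of test statistics from the fitted
#' non-central chi-square distribution, one set per row.
#'
#' @param object a `"ppe"` fit.
#' @param nsim number of sets.
#' @param seed integer seed.
#' @param s_p statistics per set (defaults to the fitted sample's size).
#' @param ... unused.
#' @return numeric matrix with `nsim` rows and `s_p` columns.
#' @export
simulate.ppe <- function(object, nsim = 1, seed = NULL, s_p = NULL, ...) {
  if (is.null(s_p)) s_p <- length(object$sample$values)
  with_seed(seed, matrix(stats::rchisq(nsim * s_p, object$df, ncp = object$lambda),
                         nrow = nsim))
}

#' Bootstrap confidence interval for the non-centrality parameter
#'
#' @param object a `"ppe"` fit.
#' @param parm unused (a PPE fit has the single parameter `lambda`).
#' @param level confidence level.
#' @param B number of bootstrap sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a 1 x 2 matrix in the style of [stats::confint()].
#' @export
confint.ppe <- function(object, parm = "lambda", level = 0.95, B = 1000,
                        seed = NULL, ...) {
  bs <- ppe_bootstrap(object, B = B, sizes = object$n_ref %||% 1L, seed = seed,
                      level = level)
  out <- matrix(bs$lambda_ci, nrow = 1,
                dimnames = list("lambda",
                                sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                           1 - (1 - level) / 2))))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
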