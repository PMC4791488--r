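## Non-central chi-square density and maximum-likelihood estimation of the
## non-centrality parameter.  This is the numerical core of the package: the
## LLR/Wald statistic of a test with k degrees of freedom follows,
## asymptotically, a central chi-square under H0 and a non-central chi-square
## with non-centrality lambda under the alternative.

#' Non-central chi-square log-density, numerically stable
#'
#' Evaluates the density of the non-central chi-square distribution in a form
#' that remains finite and accurate for non-centrality parameters up to 1e4
#' and statistics close to zero.  For `ncp > 0` the density is computed via
#' the exponentially scaled modified Bessel function,
#' \deqn{f(t; k, \lambda) = \tfrac12 e^{-(t+\lambda)/2} (t/\lambda)^{k/4-1/2}
#'   I_{k/2-1}(\sqrt{\lambda t}),}
#' which avoids the overflow/underflow of the Poisson-mixture series.
#'
#' Statistics exactly zero arise in practice from clamping small negative
#' test statistics to the null value.  For `df == 2` the density limit at zero,
#' `exp(-ncp/2)/2`, is used.  For `df < 2` the density diverges at zero as
#' `t^(df/2 - 1)`; the divergent factor does not depend on `ncp`, so it is
#' dropped and only the `ncp`-dependent limiting factor `exp(-ncp/2)` is kept.
#' This leaves any likelihood maximised over `ncp` unchanged (the objective is
#' shifted by a constant per zero-valued statistic).
#'
#' When `log = FALSE` the returned density is floored at 1e-300.
#'
#' @param x vector of nonnegative quantiles.
#' @param df degrees of freedom (k >= 1).
#' @param ncp non-centrality parameter (lambda >= 0).
#' @param log logical; return log-density?
#' @return numeric vector of (log-)density values.
#' @seealso [stats::dchisq()], against which this function agrees where both
#'   are finite.
#' @export
#' @examples
#' dncx2(3, df = 1, ncp = 7.85, log = TRUE)
#' dchisq(3, df = 1, ncp = 7.85, log = TRUE)
dncx2 <- function(x, df, ncp, log = FALSE) {
  stopifnot(df >= 1, length(df) == 1L, ncp >= 0, length(ncp) == 1L)
  out <- numeric(length(x))
  out[x < 0] <- -Inf
  ok <- which(x > 0)
  if (ncp < 1e-10) {
    out[ok] <- stats::dchisq(x[ok], df, log = TRUE)
  } else if (length(ok)) {
    t <- x[ok]
    nu <- df / 2 - 1
    st <- sqrt(ncp * t)
    out[ok] <- -log(2) - (t + ncp) / 2 + (df / 4 - 0.5) * log(t / ncp) +
      log(besselI(st, nu, expon.scaled = TRUE)) + st
  }
  zero <- which(x == 0)
  if (length(zero)) {
    out[zero] <- if (df == 2) {
      -ncp / 2 - log(2)
    } else if (df < 2) {
      -ncp / 2  # ncp-dependent limiting factor; divergent constant dropped
    } else {
      -Inf
    }
  }
  if (log) out else pmax(exp(out), 1e-300)
}

## Score of the summed ncx2 log-likelihood at lambda = 0: sum(t - k) / (2k).
## Nonpositive score means the boundary lambda = 0 is the MLE.
ncx2_score0 <- function(values, df) sum(values - df) / (2 * df)

## Summed log-likelihood objective for the non-centrality parameter.
ncx2_loglik <- function(lambda, values, df) sum(dncx2(values, df, lambda, log = TRUE))

#' @keywords internal
#' @noRd
## Scalar MLE of the non-centrality parameter on [0, Inf).
## Returns list(lambda, loglik, at_boundary, converged).
## The score test at lambda = 0 is applied first so the boundary case is exact;
## otherwise a golden-section/parabolic search (stats::optimize) is run on
## [0, max(values) + 10 df] with tolerance 1e-8.
fit_lambda <- function(values, df) {
  if (ncx2_score0(values, df) <= 0) {
    return(list(lambda = 0, loglik = ncx2_loglik(0, values, df),
                at_boundary = TRUE, converged = TRUE))
  }
  upper <- max(values) + 10 * df
  opt <- stats::optimize(ncx2_loglik, c(0, upper), values = values, df = df,
                         maximum = TRUE, tol = 1e-8)
  lam <- opt$maximum
  ## optimize never returns the exact endpoints; snap to 0 if the interior
  ## candidate does not beat the boundary (cannot happen when score0 > 0, but
  ## guards against numerically flat objectives)
  ll0 <- ncx2_loglik(0, values, df)
  if (opt$objective < ll0) {
    return(list(lambda = 0, loglik = ll0, at_boundary = TRUE, converged = TRUE))
  }
  list(lambda = lam, loglik = opt$objective, at_boundary = FALSE, converged = TRUE)
}

#' @keywords internal
#' @noRd
## Batched MLE of the non-centrality parameter over the rows of a matrix.
## For df == 1 the score function has the closed form
##   score(lambda) = (1/2) sum_s [ sqrt(t_s/lambda) tanh(sqrt(lambda t_s)) - 1 ]
## with strictly negative derivative, so a safeguarded Newton iteration from
## the moment estimate converges monotonically; all rows are updated
## simultaneously.  Other df fall back to the scalar fitter per row.
fit_lambda_batch <- function(X, df) {
  stopifnot(is.matrix(X))
  if (df != 1) return(apply(X, 1L, function(v) fit_lambda(v, df)$lambda))
  S <- ncol(X)
  score0 <- rowSums(X - 1) / 2
  lam <- pmax(rowMeans(X) - 1, 0.05)
  lam[score0 <= 0] <- 0
  active <- score0 > 0
  ## zero-valued statistics contribute -lambda/2 to the objective, i.e. a
  ## constant -1/2 to the score; drop them from the tanh term
  for (it in seq_len(60)) {
    idx <- which(active)
    if (!length(idx)) break
    l <- lam[idx]
    Xa <- X[idx, , drop = FALSE]
    r <- sqrt(Xa * l)  # column-major recycling scales row i by l[i]
    th <- tanh(r)
    sc <- 0.5 * (rowSums((r / l) * th) - S)  # zero statistics contribute -1/2 each
    ## d score / d lambda = sum(r^2 sech^2 r - r tanh r) / (4 lambda^2) <= 0
    dsc <- rowSums(r^2 / cosh(r)^2 - r * th) / (4 * l^2)
    step <- sc / dsc
    lnew <- l - step
    half <- lnew <= 0
    lnew[half] <- l[half] / 2
    lam[idx] <- lnew
    active[idx] <- abs(lnew - l) >= 1e-10
  }
  lam
}
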