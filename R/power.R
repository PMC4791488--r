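#' Critical value of the chi-square test
#'
#' The (1 - alpha) quantile of the central chi-square distribution with `df`
#' degrees of freedom; the LLR or Wald statistic rejects H0 when it exceeds
#' this value.
#'
#' @param df degrees of freedom of the test.
#' @param alpha significance level in (0, 1).
#' @return the critical value (positive scalar).
#' @export
#' @examples
#' critical_value(1, 0.05)  # 3.8415
critical_value <- function(df, alpha = 0.05) {
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  stats::qchisq(1 - alpha, df)
}

#' Power of the chi-square test at a given non-centrality parameter
#'
#' Under the alternative the test statistic follows a non-central chi-square
#' distribution; the power is the probability mass of that distribution above
#' the central chi-square critical value:
#' \deqn{\pi = 1 - F_{\chi^2}(\chi^2_{1-\alpha,k};\, k, \lambda).}
#' At `lambda = 0` this equals `alpha` (the type-I error).
#'
#' @param lambda non-centrality parameter(s), >= 0 (vectorised).
#' @param df degrees of freedom of the test.
#' @param alpha significance level in (0, 1).
#' @return power value(s) in \[0, 1\].
#' @export
#' @examples
#' power_from_lambda(7.849, df = 1, alpha = 0.05)  # ~0.80
power_from_lambda <- function(lambda, df, alpha = 0.05) {
  stopifnot(all(lambda >= 0), df >= 1, alpha > 0, alpha < 1)
  q <- critical_value(df, alpha)
  stats::pchisq(q, df, ncp = lambda, lower.tail = FALSE)
}

#' Scale a non-centrality parameter to a different study size
#'
#' For a study formed by replicating a reference design, the expected Fisher
#' information -- and with it the non-centrality parameter -- is proportional
#' to the number of subjects: `lambda_k = lambda_ref * n_k / n_ref`.
#'
#' @param lambda_ref non-centrality parameter at the reference size.
#' @param n_ref reference study size (subjects).
#' @param n_k target study size(s) (vectorised).
#' @return scaled non-centrality parameter(s).
#' @export
#' @examples
#' scale_lambda(7.85, n_ref = 200, n_k = c(100, 200, 300))
scale_lambda <- function(lambda_ref, n_ref, n_k) {
  stopifnot(lambda_ref >= 0, n_ref >= 1, all(n_k >= 1))
  lambda_ref * n_k / n_ref
}

#' Round study sizes up to the next even integer
#'
#' Study-size grids derived from fractional multipliers of a reference size
#' are rounded to the smallest even integer greater than or equal to the exact
#' value, so that a half/half covariate allocation stays exact.  Directly
#' supplied grids are used verbatim elsewhere in the package.
#'
#' @param x numeric vector of (possibly fractional) study sizes.
#' @return integer vector of even study sizes.
#' @export
#' @examples
#' even_size(110 * c(0.25, 0.5, 0.75, 1, 1.25))
even_size <- function(x) {
  stopifnot(all(x > 0))
  as.integer(2 * ceiling(x / 2))
}
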