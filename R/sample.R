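#' Assemble a cleaned sample of test statistics
#'
#' Collects raw test statistics (e.g. LLR statistics from a simulation and
#' re-estimation run) into a validated sample.  Non-finite entries are always
#' dropped.  Small negative statistics can occur through stochastic noise in
#' the estimation step; they are handled according to `negative_policy`:
#' clamped to 0 (the value under H0; conservative, the default), dropped, or
#' treated as an error.
#'
#' @param values numeric vector of raw test statistics.
#' @param df degrees of freedom of the test that produced the statistics.
#' @param negative_policy one of `"clamp"`, `"drop"`, `"error"`.
#' @return an object of class `"statistic_sample"`: a list with elements
#'   `values` (cleaned, all >= 0), `df`, `n_raw`, `n_dropped`, `n_clamped`.
#' @export
#' @examples
#' statistic_sample(c(1.2, -0.3, 4.0), df = 1)
statistic_sample <- function(values, df,
                             negative_policy = c("clamp", "drop", "error")) {
  negative_policy <- match.arg(negative_policy)
  stopifnot(is.numeric(values), df >= 1)
  if (length(values) == 0L)
    stop("no usable statistics: 'values' is empty")
  n_raw <- length(values)
  finite <- is.finite(values)
  n_dropped <- sum(!finite)
  values <- values[finite]
  neg <- values < 0
  n_clamped <- 0L
  if (any(neg)) {
    if (negative_policy == "error") {
      stop(sum(neg), " negative statistic(s) present and negative_policy = \"error\"")
    } else if (negative_policy == "clamp") {
      warning(sum(neg), " negative statistic(s) clamped to 0")
      values[neg] <- 0
      n_clamped <- sum(neg)
    } else {
      values <- values[!neg]
      n_dropped <- n_dropped + sum(neg)
    }
  }
  if (length(values) == 0L)
    stop("no usable statistics: all entries removed by preprocessing")
  structure(
    list(values = values, df = as.integer(df), n_raw = n_raw,
         n_dropped = as.integer(n_dropped), n_clamped = as.integer(n_clamped)),
    class = "statistic_sample")
}

#' @export
print.statistic_sample <- function(x, ...) {
  cat("Sample of", length(x$values), "test statistics (df =", x$df, ")\n")
  cat("  raw:", x$n_raw, " dropped:", x$n_dropped, " clamped:", x$n_clamped, "\n")
  cat("  mean:", format(mean(x$values), digits = 4),
      " range: [", format(min(x$values), digits = 4), ",",
      format(max(x$values), digits = 4), "]\n")
  invisible(x)
}

## Coerce numeric vectors (or pass through samples) for user-facing fitters.
as_statistic_sample <- function(x, df, negative_policy = "clamp") {
  if (inherits(x, "statistic_sample")) {
    if (!missing(df) && !is.null(df) && df != x$df)
      stop("'df' disagrees with the df recorded in the statistic sample")
    return(x)
  }
  statistic_sample(x, df, negative_policy)
}

#' Read test statistics from a delimited file
#'
#' Two CSV dialects (with header) are supported: a column named `statistic`
#' holding the test statistics directly, or columns `ofv_full` and
#' `ofv_reduced` holding objective-function values of the full and reduced
#' model fits.  Estimation software conventionally reports the objective
#' function as -2 times the log-likelihood, so in the second dialect the LLR
#' statistic is recovered as `ofv_reduced - ofv_full`.
#'
#' @param file path to a CSV file.
#' @param df degrees of freedom of the test.
#' @param negative_policy passed to [statistic_sample()].
#' @return a `"statistic_sample"` object.
#' @export
read_statistics <- function(file, df, negative_policy = "clamp") {
  dat <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (nrow(dat) == 0L)
    stop("no usable statistics: '", file, "' has no rows")
  if ("statistic" %in% names(dat)) {
    values <- as.numeric(dat$statistic)
  } else if (all(c("ofv_full", "ofv_reduced") %in% names(dat))) {
    values <- as.numeric(dat$ofv_reduced) - as.numeric(dat$ofv_full)
  } else {
    stop("unknown columns in '", file,
         "': expected 'statistic' or 'ofv_full'/'ofv_reduced'")
  }
  statistic_sample(values, df, negative_policy)
}
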