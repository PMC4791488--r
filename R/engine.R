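#' Simulate-and-fit statistic engines
#'
#' An engine encapsulates the "simulate a study of size n, estimate the full
#' and reduced model, return the test statistic" step that both power
#' estimators consume.  It is a function `engine(n, seed)` returning one
#' statistic, carrying attributes `"df"` (test degrees of freedom) and, when
#' a vectorised path exists, `"batch"` (`function(n, s, seed)` returning `s`
#' statistics at once, with `NA` marking failed replicates).
#'
#' `sse_engine()` builds an engine from a built-in preset (or an explicit
#' model/design pair): each replicate simulates a dataset with the reference
#' per-subject design replicated to `n` subjects and computes the LLR (or
#' Wald) statistic from full and reduced maximum-likelihood fits.  The
#' Weibull time-to-event family uses a batched Newton fitter, which makes
#' 10^4-replicate reference runs practical.
#'
#' `ncx2_engine()` is a distributional stub: it draws statistics directly
#' from the non-central chi-square distribution with the non-centrality
#' scaled as `lambda_ref * n / n_ref`.  It is the idealised engine for which
#' the parametric power estimator's assumptions hold exactly, used to
#' calibrate and test the statistical machinery separately from any
#' estimation noise.
#'
#' @param preset a preset name for [ppe_preset()], or a list with elements
#'   `model`, `design` (and optionally `df`).
#' @param statistic `"llr"` or `"wald"`.
#' @param theta_h_lower lower bound imposed on the tested effect in the full
#'   fit (boundary-constrained scenarios); `-Inf` for unconstrained.
#' @param method,nodes integration options for families that need numerical
#'   integration (see [nlmem_loglik()]).
#' @param label short name used in cache keys and summaries.
#' @return a function `engine(n, seed)` with attributes `df`, `batch`,
#'   `label`, `n_ref`.
#' @export
#' @examples
#' eng <- ncx2_engine(lambda_ref = 7.849, n_ref = 200)
#' mcpe_power_curve(eng, sizes = c(100, 200), s_m = 500, seed = 1)
sse_engine <- function(preset, statistic = c("llr", "wald"),
                       theta_h_lower = -Inf, method = "agq", nodes = 7,
                       label = NULL) {
  statistic <- match.arg(statistic)
  if (is.character(preset)) {
    if (is.null(label)) label <- preset
    preset <- ppe_preset(preset)
  }
  model <- preset$model; design <- preset$design
  if (is.null(label)) label <- paste0("sse-", model$family)
  one <- function(n, seed) {
    des <- resize_design(design, n)
    dat <- simulate_dataset(model, des, seed = seed)
    if (statistic == "wald") {
      full <- fit_model(model, dat, restricted = FALSE,
                        theta_h_lower = theta_h_lower,
                        method = method, nodes = nodes)
      return(wald_statistic(full, model, dat))
    }
    ## reduced first; the full fit starts from the reduced optimum (with the
    ## tested effect at its null value), so it can only improve the same
    ## likelihood surface and spurious negative LLR statistics -- optimiser
    ## and approximation-noise artifacts -- cannot arise
    red <- fit_model(model, dat, restricted = TRUE,
                     method = method, nodes = nodes)
    full <- fit_model(model, dat, restricted = FALSE,
                      start = red$theta_hat,
                      theta_h_lower = theta_h_lower,
                      method = method, nodes = nodes)
    if (full$loglik < red$loglik)  # full sits at the same optimum
      full$loglik <- red$loglik
    llr_statistic(full, red)
  }
  batch <- if (model$family == "tte") {
    function(n, s, seed) with_seed(seed, {
      sim <- sim_tte_batch(s, n, model$theta[1], model$theta[2],
                           model$effect, design$censor_time)
      start <- c(log(model$theta[1]), log(model$theta[2]), model$effect)
      ff <- fit_tte_batch(sim$y, sim$d, sim$z, full = TRUE, start = start)
      if (statistic == "wald") {
        tte_wald_batch(sim$y, sim$d, sim$z, ff)
      } else {
        fr <- fit_tte_batch(sim$y, sim$d, sim$z, full = FALSE, start = start)
        2 * (ff$loglik - fr$loglik)
      }
    })
  } else {
    function(n, s, seed) vapply(seq_len(s), function(r) {
      tryCatch(one(n, derive_seed(seed, r)), error = function(e) NA_real_)
    }, numeric(1))
  }
  structure(one, df = preset$df %||% 1L, batch = batch, label = label,
            n_ref = preset$n_ref %||% design$n_subjects,
            class = c("ppe_engine", "function"))
}

## Replicate the per-subject reference design at a different study size.
resize_design <- function(design, n) {
  out <- design
  out$n_subjects <- as.integer(n)
  out
}

#' @rdname sse_engine
#' @param lambda_ref non-centrality parameter at the reference size.
#' @param n_ref reference study size.
#' @param df test degrees of freedom.
#' @export
ncx2_engine <- function(lambda_ref, n_ref, df = 1, label = "ncx2-stub") {
  stopifnot(lambda_ref >= 0, n_ref >= 1, df >= 1)
  one <- function(n, seed) with_seed(seed,
    stats::rchisq(1, df, ncp = scale_lambda(lambda_ref, n_ref, n)))
  batch <- function(n, s, seed) with_seed(seed,
    stats::rchisq(s, df, ncp = scale_lambda(lambda_ref, n_ref, n)))
  structure(one, df = as.integer(df), batch = batch, label = label,
            n_ref = as.integer(n_ref), class = c("ppe_engine", "function"))
}

#' Run a stochastic simulation-and-estimation study
#'
#' Generates `s` test statistics from an engine at study size `n` -- the raw
#' material for [ppe()] and [mcpe()].
#'
#' @param engine an engine from [sse_engine()] or [ncx2_engine()].
#' @param n study size.
#' @param s number of replicates.
#' @param seed integer seed.
#' @param warn_failures warn when replicates failed?
#' @return numeric vector of `s` statistics (`NA` = failed replicate).
#' @export
sse_statistics <- function(engine, n, s, seed, warn_failures = TRUE) {
  stats <- engine_statistics(engine, n, s, seed)
  nf <- sum(!is.finite(stats))
  if (warn_failures && nf > 0)
    warning(nf, " of ", s, " replicates failed at study size ", n)
  stats
}
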