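#' Declare a mixed-effects model for the simulate-estimate engine
#'
#' Describes one of the built-in model families together with its fixed
#' effects, random-effect covariance, residual variance and the tested
#' covariate effect.  The tested parameter `theta_H` always enters the model
#' through the family's covariate submodel and is fixed at 0 in reduced fits.
#'
#' Families:
#' \describe{
#'   \item{`binary`}{repeated Bernoulli response with
#'     `P(y = 1) = expit(b + a t)`, `b = theta1 + eta1`,
#'     `a = (theta2 + eta2)(1 - theta_H z)`; 2 random effects.}
#'   \item{`tte`}{single time-to-event per subject with Weibull hazard
#'     `h(t) = lam * gam * (lam t)^(gam - 1)`, `lam = theta1 exp(theta_H z)`,
#'     `gam = theta2`, right-censored at the design's `censor_time`; no random
#'     effects.}
#'   \item{`count`}{repeated Poisson counts with rate
#'     `lam(t) = b + A (1 - exp(-k t))`, `b = theta1 e^eta1`,
#'     `A = theta2 e^eta2`, `k = theta3 e^(eta3 + theta_H z)`;
#'     3 random effects.}
#'   \item{`gaussian_linear`}{continuous response
#'     `y = S0 + alpha t + A (e^(-koff t) - e^(-kon t)) + eps` with
#'     `S0 = theta1 + eta1`, `alpha = (theta2 + eta2)(1 - theta_H z)`,
#'     `A = theta3`, `koff = theta4`, `kon = theta5`; linear in the 2 random
#'     effects, so the marginal likelihood is an exact multivariate normal.}
#' }
#'
#' @param family model family, see Details.
#' @param theta numeric vector of fixed effects (family-specific length).
#' @param omega random-effect covariance matrix (symmetric PSD), or `NULL`
#'   for families without random effects.
#' @param sigma residual variance (scalar), or `NULL` for discrete families.
#' @param effect the simulated value of the tested effect `theta_H^*`.
#' @param covariate `"dichotomous"` (0/1 split half/half, assigned
#'   deterministically by alternation) or `"standard_normal"`.
#' @return object of class `"model_spec"`.
#' @export
model_spec <- function(family = c("binary", "tte", "count", "gaussian_linear"),
                       theta, omega = NULL, sigma = NULL, effect = 0,
                       covariate = c("dichotomous", "standard_normal")) {
  family <- match.arg(family)
  covariate <- match.arg(covariate)
  n_theta <- c(binary = 2L, tte = 2L, count = 3L, gaussian_linear = 5L)[family]
  n_eta <- c(binary = 2L, tte = 0L, count = 3L, gaussian_linear = 2L)[family]
  if (length(theta) != n_theta)
    stop("family '", family, "' needs ", n_theta, " fixed effects")
  if (n_eta > 0L) {
    if (is.null(omega)) stop("family '", family, "' needs an omega matrix")
    omega <- as.matrix(omega)
    if (nrow(omega) != n_eta || ncol(omega) != n_eta)
      stop("omega must be ", n_eta, " x ", n_eta)
    if (any(abs(omega - t(omega)) > 1e-12))
      stop("omega must be symmetric")
    if (any(eigen(omega, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      stop("omega must be positive semi-definite")
  } else if (!is.null(omega)) {
    stop("family '", family, "' has no random effects; omega must be NULL")
  }
  if (family == "gaussian_linear") {
    if (is.null(sigma) || sigma <= 0)
      stop("family 'gaussian_linear' needs a positive residual variance")
  } else if (!is.null(sigma)) {
    stop("family '", family, "' has no residual variance; sigma must be NULL")
  }
  structure(list(family = family, theta = as.numeric(theta), omega = omega,
                 sigma = sigma, effect = as.numeric(effect),
                 covariate = covariate),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Mixed-effects model spec: family", x$family, "\n")
  cat("  theta:", paste(format(x$theta, digits = 4), collapse = ", "),
      "  tested effect:", x$effect, "(", x$covariate, "covariate )\n")
  invisible(x)
}

#' Declare a replicable study design
#'
#' The per-subject design (observation times, censoring horizon) that is
#' replicated across subjects; power curves across study sizes assume this
#' reference design is replicated, which is what makes the non-centrality
#' parameter proportional to `n_subjects`.
#'
#' @param n_subjects number of subjects N.
#' @param times strictly increasing nonnegative observation times (for the
#'   `tte` family, leave `NULL`; the single response time is the event or
#'   censoring time itself).
#' @param censor_time right-censoring horizon (required for `tte`).
#' @param dose administered dose, kept for bookkeeping only.
#' @return object of class `"study_design"`.
#' @export
study_design <- function(n_subjects, times = NULL, censor_time = NULL,
                         dose = NULL) {
  stopifnot(n_subjects >= 1)
  if (!is.null(times)) {
    stopifnot(all(times >= 0), !is.unsorted(times, strictly = TRUE))
  }
  if (!is.null(censor_time)) stopifnot(censor_time > 0)
  structure(list(n_subjects = as.integer(n_subjects), times = times,
                 censor_time = censor_time, dose = dose),
            class = "study_design")
}

## ---------------------------------------------------------------------------
## Preset registry: the evaluation models with their reference parameter
## values and designs, plus the Alzheimer disease-progression trial example
## at three study lengths.

preset_registry <- function() {
  ## Disease-progression trial: visits every 6 months; time is measured in
  ## years (the progression rate and the placebo onset/offset rate constants
  ## are per-year values).
  alz <- function(months) {
    list(model = model_spec(
           "gaussian_linear",
           theta = c(56.4, 4.83, -20, 2.77, 1.73),
           omega = matrix(c(14.3, -1.2, -1.2, 6.1), 2, 2),
           sigma = 7.9, effect = 0.3, covariate = "dichotomous"),
         design = study_design(100, times = seq(0, months / 12, by = 0.5)),
         df = 1L, n_ref = 100L)
  }
  list(
    binary = list(
      model = model_spec("binary", theta = c(-1, 4),
                         omega = diag(c(0.4, 4)), effect = 0.3,
                         covariate = "dichotomous"),
      design = study_design(110, times = seq(0, 1, length.out = 20)),
      df = 1L, n_ref = 110L),
    tte = list(
      model = model_spec("tte", theta = c(0.2, 2), effect = 0.4,
                         covariate = "dichotomous"),
      design = study_design(200, censor_time = 10),
      df = 1L, n_ref = 200L),
    count = list(
      model = model_spec("count", theta = c(1, 4, 2),
                         omega = diag(c(0.09, 0.09, 0.09)), effect = 0.3,
                         covariate = "standard_normal"),
      design = study_design(160, times = seq(0, 1, length.out = 10)),
      df = 1L, n_ref = 160L),
    alzheimer12 = alz(12), alzheimer18 = alz(18), alzheimer24 = alz(24))
}

#' Built-in model and design presets
#'
#' Returns the model specification, reference study design, test degrees of
#' freedom and reference study size for one of the built-in presets:
#' `"binary"`, `"tte"`, `"count"` (the evaluation models) and
#' `"alzheimer12"`, `"alzheimer18"`, `"alzheimer24"` (the disease-progression
#' trial example with visits every 6 months up to 12, 18 or 24 months).
#'
#' The ODE-based `"pk"` and `"pkpd"` model names are registered but have no
#' internal estimator; requesting them raises an error.  Statistics produced
#' for such models by external estimation software can still be analysed via
#' [read_statistics()] and [ppe()].
#'
#' @param name preset name.
#' @return list with elements `model`, `design`, `df`, `n_ref`.
#' @export
#' @examples
#' ppe_preset("tte")
ppe_preset <- function(name) {
  if (name %in% c("pk", "pkpd"))
    stop("preset '", name, "' (ODE-based) is not implemented -- ",
         "supply its test statistics via file (read_statistics) instead")
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; available: ",
         paste(c(names(reg), "pk", "pkpd"), collapse = ", "))
  reg[[name]]
}
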