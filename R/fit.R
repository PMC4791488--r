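## Maximum-likelihood fitting of the engine models.
##
## Optimisation runs on a transformed scale: log for positive parameters
## (rates, shape, variances) and a Cholesky parameterisation for the 2x2
## random-effect covariance of the gaussian_linear family; the tested effect
## thetaH is untransformed so box constraints on it (boundary-constrained
## hypotheses) can be imposed directly.  Starting values are the simulating
## truths -- standard practice in simulation studies mirroring a stochastic
## simulation-and-estimation workflow -- with optional jitter.

## Transform bookkeeping: which natural parameters are log-transformed.
log_transformed <- function(family) {
  switch(family,
    tte = c("theta1", "gamma"),
    binary = c("omega1", "omega2"),
    count = c("theta1", "theta2", "theta3", "omega1", "omega2", "omega3"),
    gaussian_linear = c("theta4", "theta5", "sigma2"))
}

## gaussian_linear replaces (omega11, omega22, omega12) by the lower Cholesky
## (log l11, l21, log l22) so any iterate maps to a positive-definite Omega.
pack_params <- function(family, params) {
  p <- params
  if (family == "gaussian_linear") {
    l11 <- sqrt(p[["omega11"]])
    l21 <- p[["omega12"]] / l11
    l22 <- sqrt(p[["omega22"]] - l21^2)
    p <- c(p[!names(p) %in% c("omega11", "omega22", "omega12")],
           chol1 = log(l11), chol2 = l21, chol3 = log(l22))
  }
  lt <- log_transformed(family)
  p[lt] <- log(p[lt])
  p
}

unpack_params <- function(family, packed) {
  p <- packed
  lt <- log_transformed(family)
  p[lt] <- exp(p[lt])
  if (family == "gaussian_linear") {
    l11 <- exp(p[["chol1"]]); l21 <- p[["chol2"]]; l22 <- exp(p[["chol3"]])
    p <- c(p[!names(p) %in% c("chol1", "chol2", "chol3")],
           omega11 = l11^2, omega22 = l21^2 + l22^2, omega12 = l11 * l21)
  }
  p[nlmem_param_names(family)]
}

data_fingerprint <- function(data) {
  if (inherits(data, "nlmem_matrices")) return(data$fingerprint)
  c(nrow(data), sum(data$dv), sum(data$time), sum(data$covariate))
}

#' Fit an engine model to a dataset by maximum likelihood
#'
#' Maximises the marginal log-likelihood ([nlmem_loglik()]) over the free
#' parameters with a quasi-Newton optimiser on a transformed scale.  In a
#' restricted ("reduced model") fit the tested effect `thetaH` is fixed at its
#' null value 0; the full/reduced pair feeds the LLR statistic.
#'
#' @param model a [model_spec()].
#' @param data an `"nlmem_data"` data frame of the same family.
#' @param restricted fix `thetaH = 0`?
#' @param start named starting values on the natural scale; defaults to the
#'   simulating truths recorded in `model` (with `thetaH = 0` when
#'   restricted).
#' @param theta_h_lower lower bound for `thetaH` (e.g. 0 to force the null
#'   onto the parameter-space boundary); `-Inf` for an unconstrained fit.
#' @param jitter standard deviation of optional Gaussian jitter added to the
#'   transformed starting values.
#' @param method,nodes integration options passed to [nlmem_loglik()].
#' @return object of class `"nlmem_fit"`: list with `theta_hat` (named,
#'   natural scale; restricted fits report `thetaH = 0`), `loglik`,
#'   `restricted`, `converged`, `n_iter`, `family`.
#' @export
#' @examples
#' p <- ppe_preset("tte")
#' d <- simulate_dataset(p$model, p$design, seed = 1)
#' full <- fit_model(p$model, d)
#' red <- fit_model(p$model, d, restricted = TRUE)
#' llr_statistic(full, red)
fit_model <- function(model, data, restricted = FALSE, start = NULL,
                      theta_h_lower = -Inf, jitter = 0,
                      method = "agq", nodes = 7) {
  family <- model$family
  if (family != "tte") data <- nlmem_matrices(data)  # reshape once, not per eval
  if (is.null(start)) start <- nlmem_true_params(model)
  if (restricted) start["thetaH"] <- 0
  packed <- pack_params(family, start)
  free <- if (restricted) setdiff(names(packed), "thetaH") else names(packed)
  if (jitter > 0) packed[free] <- packed[free] + stats::rnorm(length(free), 0, jitter)
  fixed <- packed[setdiff(names(packed), free)]
  warm <- new.env(parent = emptyenv())  # carries inner modes across evals
  negll <- function(p) {
    full_p <- c(stats::setNames(p, free), fixed)
    val <- tryCatch(
      nlmem_loglik(model, unpack_params(family, full_p), data,
                   method = method, nodes = nodes, warm = warm),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else -val
  }
  lower <- rep(-Inf, length(free))
  if ("thetaH" %in% free && is.finite(theta_h_lower))
    lower[match("thetaH", free)] <- theta_h_lower
  opt <- stats::nlminb(packed[free], negll, lower = lower,
                       control = list(iter.max = 500, eval.max = 1000,
                                      rel.tol = 1e-10))
  est <- unpack_params(family, c(stats::setNames(opt$par, free), fixed))
  structure(list(theta_hat = est, loglik = -opt$objective,
                 restricted = restricted, converged = opt$convergence == 0,
                 n_iter = opt$iterations, message = opt$message,
                 family = family, theta_h_lower = theta_h_lower,
                 fingerprint = data_fingerprint(data),
                 method = method, nodes = nodes),
            class = "nlmem_fit")
}

#' @export
print.nlmem_fit <- function(x, digits = 4, ...) {
  cat(if (x$restricted) "Reduced" else "Full", x$family,
      "model fit (logLik", format(x$loglik, digits = digits), ")\n")
  print(round(x$theta_hat, digits))
  if (!x$converged) cat("  ** optimiser did not report convergence **\n")
  invisible(x)
}

#' Likelihood-ratio test statistic from a full/reduced fit pair
#'
#' Returns `2 * (loglik_full - loglik_reduced)`.  Tiny negative values (above
#' -1e-6), which arise from optimiser tolerance, are clamped to 0; more
#' negative values are returned as-is so that [statistic_sample()] can apply
#' its negative-statistic policy.
#'
#' @param full,reduced `"nlmem_fit"` objects for the same data, `reduced`
#'   nested in `full`.
#' @return the LLR statistic (scalar).
#' @export
llr_statistic <- function(full, reduced) {
  stopifnot(inherits(full, "nlmem_fit"), inherits(reduced, "nlmem_fit"))
  if (!reduced$restricted || full$restricted)
    stop("'full' must be unrestricted and 'reduced' restricted")
  if (!isTRUE(all.equal(full$fingerprint, reduced$fingerprint)))
    stop("full and reduced fits are not from the same dataset")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < 0 && stat > -1e-6) stat <- 0
  stat
}

#' Wald test statistic
#'
#' `(thetaH_hat - null)^2 / Var(thetaH_hat)`, with the variance taken from the
#' inverse of the numerically differentiated observed information at the full
#' estimate (computed on the transformed optimisation scale, on which the
#' tested effect is an untransformed coordinate, so its marginal variance is
#' unaffected by the reparameterisation of the nuisance parameters).
#'
#' @param full a converged unrestricted `"nlmem_fit"`.
#' @param model the [model_spec()] used for the fit.
#' @param data the fitted dataset.
#' @param null_value null value of the tested effect.
#' @return the Wald statistic (scalar).
#' @export
wald_statistic <- function(full, model, data, null_value = 0) {
  stopifnot(inherits(full, "nlmem_fit"), !full$restricted)
  if (!full$converged) stop("the full fit did not converge")
  if (model$family != "tte") data <- nlmem_matrices(data)
  packed <- pack_params(model$family, full$theta_hat)
  nm <- names(packed)
  negll <- function(p) {
    val <- tryCatch(
      nlmem_loglik(model, unpack_params(model$family, stats::setNames(p, nm)),
                   data, method = full$method, nodes = full$nodes),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else -val
  }
  H <- stats::optimHess(packed, negll)
  V <- tryCatch(solve(H), error = function(e)
    stop("singular observed information: tested effect not identifiable"))
  v <- V[match("thetaH", nm), match("thetaH", nm)]
  if (!is.finite(v) || v <= 0)
    stop("singular observed information: tested effect not identifiable")
  (full$theta_hat[["thetaH"]] - null_value)^2 / v
}

#' Standard errors of a fitted model from the observed information
#'
#' Inverts the numerically differentiated observed information at the
#' estimate (on the optimisation scale) and maps the standard errors back to
#' the natural scale by the delta method.  Entries whose natural-scale
#' standard error is not a simple transform of an optimisation coordinate
#' (the covariance entries of a Cholesky-parameterised Omega) are `NA`.
#'
#' @param model the [model_spec()] used for the fit.
#' @param fit an unrestricted `"nlmem_fit"`.
#' @param data the fitted dataset.
#' @return named vector of standard errors aligned with `fit$theta_hat`.
#' @export
nlmem_se <- function(model, fit, data) {
  stopifnot(inherits(fit, "nlmem_fit"), !fit$restricted)
  family <- model$family
  if (family != "tte") data <- nlmem_matrices(data)
  packed <- pack_params(family, fit$theta_hat)
  nm <- names(packed)
  negll <- function(p) {
    val <- tryCatch(
      nlmem_loglik(model, unpack_params(family, stats::setNames(p, nm)), data,
                   method = fit$method, nodes = fit$nodes),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else -val
  }
  H <- stats::optimHess(packed, negll)
  V <- solve(H)
  se_packed <- sqrt(pmax(diag(V), 0))
  names(se_packed) <- nm
  out <- rep(NA_real_, length(fit$theta_hat))
  names(out) <- names(fit$theta_hat)
  lt <- log_transformed(family)
  for (p in names(out)) {
    if (p %in% lt) {
      out[p] <- se_packed[p] * fit$theta_hat[[p]]  # delta method for log scale
    } else if (p %in% nm) {
      out[p] <- se_packed[p]
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Batched Weibull fitting: all replicates of a simulation study iterate a
## safeguarded Newton step simultaneously (analytic gradient and Hessian of
## the censored Weibull log-likelihood in (log theta1, log gamma, thetaH)).
## Agrees with fit_model() on the same data to optimiser tolerance and turns
## 10^4-replicate studies into a few seconds of work.

## y, d(event indicator), z: R x N matrices. Returns per-replicate loglik and
## estimates; `full = FALSE` fixes thetaH at 0.
fit_tte_batch <- function(y, d, z, full = TRUE, start = c(log(0.2), log(2), 0.4)) {
  R <- nrow(y); N <- ncol(y)
  ly <- log(y)
  a <- rep(start[1], R); g <- rep(start[2], R)
  b <- rep(if (full) start[3] else 0, R)
  llfun <- function(a, g, b) {
    gam <- exp(g); m <- a + b * z + ly
    rowSums(d * (g - ly + gam * m)) - rowSums(exp(pmin(gam * m, 700)))
  }
  ll <- llfun(a, g, b)
  an <- a; gn <- g; bn <- b
  for (it in seq_len(100)) {
    gam <- exp(g)
    m <- a + b * z + ly
    u <- exp(pmin(gam * m, 700))
    du <- d - u
    ga <- gam * rowSums(du)
    gg <- rowSums(d * (1 + gam * m)) - gam * rowSums(m * u)
    Haa <- -gam^2 * rowSums(u)
    Hag <- ga - gam^2 * rowSums(m * u)
    Hgg <- gam * rowSums(d * m) - gam * rowSums(m * u) - gam^2 * rowSums(m^2 * u)
    if (full) {
      gb <- gam * rowSums(z * du)
      Hab <- -gam^2 * rowSums(z * u)
      Hbb <- -gam^2 * rowSums(z^2 * u)
      Hbg <- gb - gam^2 * rowSums(z * m * u)
      s <- solve3(-Haa, -Hag, -Hab, -Hgg, -Hbg, -Hbb, ga, gg, gb)
      s1 <- s$x1; s2 <- s$x2; s3 <- s$x3
    } else {
      det2 <- Haa * Hgg - Hag^2
      s1 <- -(Hgg * ga - Hag * gg) / det2
      s2 <- -(Haa * gg - Hag * ga) / det2
      s3 <- 0
    }
    for (h in seq_len(30)) {
      an <- a + s1; gn <- g + s2; bn <- if (full) b + s3 else b
      lln <- llfun(an, gn, bn)
      bad <- !is.finite(lln) | (lln < ll - 1e-9)
      if (!any(bad)) break
      s1[bad] <- s1[bad] / 2; s2[bad] <- s2[bad] / 2
      if (full) s3[bad] <- s3[bad] / 2
    }
    moved <- max(abs(an - a), abs(gn - g), abs(bn - b))
    a <- an; g <- gn; b <- bn; ll <- lln
    if (moved < 1e-9) break
  }
  ## observed information on the iteration scale, for the batched Wald test
  list(theta1 = exp(a), gamma = exp(g), thetaH = b, loglik = ll,
       a = a, g = g)
}

## Batched Wald statistic: Var(thetaH) from the closed-form inverse of the
## analytic 3x3 observed information at the full optimum.
tte_wald_batch <- function(y, d, z, fit) {
  gam <- exp(fit$g)
  m <- fit$a + fit$thetaH * z + log(y)
  u <- exp(pmin(gam * m, 700))
  du <- d - u
  ga <- gam * rowSums(du)
  gb <- gam * rowSums(z * du)
  Haa <- -gam^2 * rowSums(u)
  Hab <- -gam^2 * rowSums(z * u)
  Hbb <- -gam^2 * rowSums(z^2 * u)
  Hag <- ga - gam^2 * rowSums(m * u)
  Hbg <- gb - gam^2 * rowSums(z * m * u)
  Hgg <- gam * rowSums(d * m) - gam * rowSums(m * u) - gam^2 * rowSums(m^2 * u)
  ## [(-H)^{-1}]_bb = cofactor / det
  det3 <- det3x3(-Haa, -Hag, -Hab, -Hgg, -Hbg, -Hbb)
  vbb <- (Haa * Hgg - Hag^2) / det3
  fit$thetaH^2 / vbb
}

## Simulate R replicates of the tte preset design at size n in matrix form.
sim_tte_batch <- function(R, n, theta1, gamma, effect, censor_time) {
  z <- matrix(rep(c(0, 1), length.out = n), R, n, byrow = TRUE)
  lam <- theta1 * exp(effect * z)
  y <- (-log(matrix(stats::runif(R * n), R, n)))^(1 / gamma) / lam
  d <- y < censor_time
  y[!d] <- censor_time
  list(y = y, d = d + 0, z = z)
}
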