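## Marginal log-likelihoods for the engine's model families.
##
## Parameter vectors are on the natural scale and named:
##   tte:             theta1, gamma, thetaH
##   binary:          theta1, theta2, thetaH, omega1, omega2     (variances)
##   count:           theta1..theta3, thetaH, omega1..omega3     (variances)
##   gaussian_linear: theta1..theta5, thetaH, omega11, omega22, omega12, sigma2
##
## tte and gaussian_linear likelihoods are exact (closed-form Weibull and
## multivariate-normal marginals); binary uses subject-mode-centred adaptive
## Gauss-Hermite quadrature over its 2 random effects (default 7 nodes per
## dimension, configurable, with "laplace" as the 1-node special case); count
## uses a Laplace approximation over its 3 random effects.

nlmem_param_names <- function(family) {
  switch(family,
    tte = c("theta1", "gamma", "thetaH"),
    binary = c("theta1", "theta2", "thetaH", "omega1", "omega2"),
    count = c("theta1", "theta2", "theta3", "thetaH",
              "omega1", "omega2", "omega3"),
    gaussian_linear = c("theta1", "theta2", "theta3", "theta4", "theta5",
                        "thetaH", "omega11", "omega22", "omega12", "sigma2"))
}

#' Simulating truth of a model spec as a named parameter vector
#'
#' Returns the parameter vector (in the layout used by [nlmem_loglik()] and
#' [fit_model()]) whose entries are the values the model simulates under,
#' including the tested effect.  Used as the default starting values of fits.
#'
#' @param model a [model_spec()].
#' @return named numeric vector.
#' @export
nlmem_true_params <- function(model) {
  th <- model$theta; om <- model$omega
  p <- switch(model$family,
    tte = c(th[1], th[2], model$effect),
    binary = c(th[1], th[2], model$effect, om[1, 1], om[2, 2]),
    count = c(th[1], th[2], th[3], model$effect, om[1, 1], om[2, 2], om[3, 3]),
    gaussian_linear = c(th, model$effect, om[1, 1], om[2, 2], om[1, 2],
                        model$sigma))
  stats::setNames(p, nlmem_param_names(model$family))
}

#' Marginal log-likelihood of an engine model
#'
#' Evaluates the marginal log-likelihood of a simulated (or compatible)
#' dataset at a given parameter vector.  See the package source header of
#' `loglik.R` for the per-family parameter layout; [nlmem_true_params()] is
#' not exported, but [fit_model()] reports estimates in the same layout.
#'
#' @param model a [model_spec()] (defines the family).
#' @param params named numeric parameter vector on the natural scale.
#' @param data an `"nlmem_data"` data frame for the same family.
#' @param method integration method for the binary family: `"agq"` (adaptive
#'   Gauss-Hermite) or `"laplace"`.
#' @param nodes Gauss-Hermite nodes per random-effect dimension.
#' @return the scalar marginal log-likelihood.
#' @export
nlmem_loglik <- function(model, params, data, method = "agq", nodes = 7,
                         warm = NULL) {
  check_domain(model$family, params)
  switch(model$family,
    tte = ll_tte(params, data),
    binary = ll_binary(params, data, method = method, nodes = nodes,
                       warm = warm),
    count = ll_count(params, data),
    gaussian_linear = ll_gaussian(params, data))
}

check_domain <- function(family, params) {
  pos <- switch(family,
    tte = c("theta1", "gamma"),
    binary = c("omega1", "omega2"),
    count = c("theta1", "theta2", "theta3", "omega1", "omega2", "omega3"),
    gaussian_linear = c("theta4", "theta5", "omega11", "omega22", "sigma2"))
  bad <- pos[params[pos] <= 0]
  if (length(bad))
    stop("parameter(s) outside the family domain (must be > 0): ",
         paste(bad, collapse = ", "))
  if (family == "gaussian_linear" &&
      params["omega12"]^2 >= params["omega11"] * params["omega22"])
    stop("omega must be positive definite: |omega12| < sqrt(omega11*omega22)")
  invisible(TRUE)
}

## --- time-to-event: exact Weibull likelihood with right censoring ----------
ll_tte <- function(params, data) {
  lam <- params[["theta1"]] * exp(params[["thetaH"]] * data$covariate)
  gam <- params[["gamma"]]
  y <- data$dv
  d <- data$cens == 0
  u <- (lam * y)^gam
  sum(d) * log(gam) + sum(gam * log(lam[d] * y[d]) - log(y[d])) - sum(u)
}

## --- gaussian_linear: exact multivariate-normal marginal -------------------
## Per subject: y ~ N(mu, Z Omega Z' + sigma2 I) with Z = [1, (1 - thetaH z) t].
ll_gaussian <- function(params, data) {
  m <- nlmem_matrices(data)
  th <- params
  Omega <- matrix(c(th[["omega11"]], th[["omega12"]],
                    th[["omega12"]], th[["omega22"]]), 2, 2)
  tt <- m$times; J <- m$J
  pbo <- th[["theta3"]] * (exp(-th[["theta4"]] * tt) - exp(-th[["theta5"]] * tt))
  ll <- 0
  for (zv in unique(m$z)) {
    idx <- which(m$z == zv)
    cz <- 1 - th[["thetaH"]] * zv
    Z <- cbind(1, cz * tt)
    V <- Z %*% Omega %*% t(Z) + diag(th[["sigma2"]], J)
    mu <- th[["theta1"]] + th[["theta2"]] * cz * tt + pbo
    R <- t(m$Y[idx, , drop = FALSE]) - mu          # J x n_group residuals
    cV <- chol(V)
    q <- backsolve(cV, R, transpose = TRUE)        # whitened residuals
    ll <- ll - length(idx) * (sum(log(diag(cV))) + J / 2 * log(2 * pi)) -
      0.5 * sum(q^2)
  }
  ll
}

## --- binary: adaptive Gauss-Hermite over 2 random effects ------------------
## Finds the per-subject posterior mode of eta by vectorised Newton iterations,
## then integrates exp(g) with mode-centred, curvature-scaled GH nodes; the
## Laplace method is the analytic 1-node limit.
## `warm` (optional environment) carries the previous call's posterior modes;
## the inner problem is strictly concave (Bernoulli log-likelihood plus a
## Gaussian prior), so warm starts change only the iteration count, never the
## mode found.  Used by fit_model, where successive objective evaluations
## differ by small parameter steps.
ll_binary <- function(params, data, method = c("agq", "laplace"), nodes = 7,
                      warm = NULL) {
  method <- match.arg(method)
  m <- nlmem_matrices(data)
  th1 <- params[["theta1"]]; th2 <- params[["theta2"]]
  bH <- params[["thetaH"]]
  om1 <- params[["omega1"]]; om2 <- params[["omega2"]]
  Y <- m$Y; tt <- m$times; N <- m$N; J <- m$J
  cz <- 1 - bH * m$z
  ttm <- matrix(tt, N, J, byrow = TRUE)
  ## conditional log-likelihood + log prior, and derivatives wrt (eta1, eta2)
  gval <- function(e1, e2) {
    lin <- (th1 + e1) + (th2 + e2) * cz * ttm
    rowSums(Y * lin - log1p(exp(lin))) -
      e1^2 / (2 * om1) - e2^2 / (2 * om2) - 0.5 * log(4 * pi^2 * om1 * om2)
  }
  newton <- function(e1, e2) {
    for (it in seq_len(50)) {
      lin <- (th1 + e1) + (th2 + e2) * cz * ttm
      P <- plogis(lin)
      R <- Y - P; W <- P * (1 - P)
      g1 <- rowSums(R) - e1 / om1
      g2 <- cz * rowSums(R * ttm) - e2 / om2
      h11 <- -rowSums(W) - 1 / om1
      h12 <- -cz * rowSums(W * ttm)
      h22 <- -cz^2 * rowSums(W * ttm^2) - 1 / om2
      det <- h11 * h22 - h12^2
      d1 <- (h22 * g1 - h12 * g2) / det
      d2 <- (h11 * g2 - h12 * g1) / det
      e1 <- e1 - d1; e2 <- e2 - d2
      if (!all(is.finite(c(e1, e2)))) return(NULL)
      if (max(abs(c(d1, d2))) < 1e-10) break
    }
    list(e1 = e1, e2 = e2)
  }
  mode <- NULL
  if (!is.null(warm) && !is.null(warm$e1)) mode <- newton(warm$e1, warm$e2)
  if (is.null(mode)) mode <- newton(numeric(N), numeric(N))
  if (is.null(mode)) stop("inner mode search diverged for the binary family")
  e1 <- mode$e1; e2 <- mode$e2
  if (!is.null(warm)) { warm$e1 <- e1; warm$e2 <- e2 }
  lin <- (th1 + e1) + (th2 + e2) * cz * ttm
  P <- plogis(lin); W <- P * (1 - P)
  h11 <- -rowSums(W) - 1 / om1
  h12 <- -cz * rowSums(W * ttm)
  h22 <- -cz^2 * rowSums(W * ttm^2) - 1 / om2
  det <- h11 * h22 - h12^2
  if (any(!is.finite(det)))
    stop("non-finite quadrature curvature for subject ",
         which(!is.finite(det))[1])
  if (method == "laplace" || nodes == 1) {
    ll_i <- gval(e1, e2) + log(2 * pi) - 0.5 * log(det)
  } else {
    gh <- pracma::gaussHermite(nodes)
    ## chol factor of (-H)^{-1} = [-h22, h12; h12, -h11] / det(-H)
    L11 <- sqrt(-h22 / det)
    L21 <- h12 / det / L11
    L22 <- sqrt(-h11 / det - L21^2)
    xg <- expand.grid(q1 = seq_len(nodes), q2 = seq_len(nodes))
    x1 <- gh$x[xg$q1]; x2 <- gh$x[xg$q2]
    lw <- log(gh$w[xg$q1]) + log(gh$w[xg$q2]) + x1^2 + x2^2
    Q <- length(x1)
    terms <- matrix(NA_real_, N, Q)
    for (q in seq_len(Q)) {
      eq1 <- e1 + sqrt(2) * L11 * x1[q]
      eq2 <- e2 + sqrt(2) * (L21 * x1[q] + L22 * x2[q])
      terms[, q] <- gval(eq1, eq2) + lw[q]
    }
    mx <- apply(terms, 1L, max)
    ll_i <- mx + log(rowSums(exp(terms - mx))) + log(2) +
      log(L11 * L22)                       # 2^{d/2} |L| with d = 2
  }
  if (any(!is.finite(ll_i)))
    stop("non-finite marginal likelihood for subject ",
         which(!is.finite(ll_i))[1])
  sum(ll_i)
}

## --- count: Laplace approximation over 3 random effects --------------------
ll_count <- function(params, data) {
  m <- nlmem_matrices(data)
  th1 <- params[["theta1"]]; th2 <- params[["theta2"]]; th3 <- params[["theta3"]]
  bH <- params[["thetaH"]]
  om <- c(params[["omega1"]], params[["omega2"]], params[["omega3"]])
  Y <- m$Y; tt <- m$times; N <- m$N; J <- m$J
  ttm <- matrix(tt, N, J, byrow = TRUE)
  zeff <- bH * m$z
  lgam <- rowSums(lgamma(Y + 1))
  rate <- function(e1, e2, e3) {
    b <- th1 * exp(e1); A <- th2 * exp(e2); k <- th3 * exp(e3 + zeff)
    ek <- exp(-k * ttm)
    list(lam = b + A * (1 - ek), b = b, A = A, k = k, ek = ek)
  }
  gval <- function(e1, e2, e3) {
    r <- rate(e1, e2, e3)
    rowSums(Y * log(r$lam) - r$lam) - lgam -
      (e1^2 / om[1] + e2^2 / om[2] + e3^2 / om[3]) / 2 -
      0.5 * log((2 * pi)^3 * prod(om))
  }
  e1 <- numeric(N); e2 <- numeric(N); e3 <- numeric(N)
  g_old <- gval(e1, e2, e3)
  for (it in seq_len(100)) {
    r <- rate(e1, e2, e3)
    lam <- r$lam
    c1 <- Y / lam - 1                       # d/dlam of y log lam - lam
    w <- Y / lam^2                          # -d2/dlam2
    dl1 <- r$b                              # dlam/deta1  (N vector, same all j)
    dl2 <- r$A * (1 - r$ek)                 # dlam/deta2  (N x J)
    dl3 <- r$A * ttm * r$k * r$ek           # dlam/deta3  (N x J)
    g1 <- rowSums(c1) * dl1 - e1 / om[1]
    g2 <- rowSums(c1 * dl2) - e2 / om[2]
    g3 <- rowSums(c1 * dl3) - e3 / om[3]
    ## scoring-style curvature (the second-derivative-of-lambda terms are
    ## dropped): always positive definite, so the step is an ascent direction
    s11 <- rowSums(w) * dl1^2 + 1 / om[1]
    s22 <- rowSums(w * dl2^2) + 1 / om[2]
    s33 <- rowSums(w * dl3^2) + 1 / om[3]
    s12 <- rowSums(w * dl2) * dl1
    s13 <- rowSums(w * dl3) * dl1
    s23 <- rowSums(w * dl2 * dl3)
    s <- solve3(s11, s12, s13, s22, s23, s33, g1, g2, g3)
    step <- 1
    repeat {
      n1 <- e1 + step * s$x1; n2 <- e2 + step * s$x2; n3 <- e3 + step * s$x3
      g_new <- gval(n1, n2, n3)
      if (all(is.finite(g_new)) && all(g_new >= g_old - 1e-10)) break
      step <- step / 2
      if (step < 1e-6) { n1 <- e1; n2 <- e2; n3 <- e3; g_new <- g_old; break }
    }
    moved <- max(abs(c(n1 - e1, n2 - e2, n3 - e3)))
    e1 <- n1; e2 <- n2; e3 <- n3; g_old <- g_new
    if (moved < 1e-9) break
  }
  ## observed curvature at the mode for the Laplace determinant; where it is
  ## (numerically) indefinite, fall back to the positive-definite scoring
  ## curvature of that subject
  r <- rate(e1, e2, e3)
  lam <- r$lam; c1 <- Y / lam - 1; w <- Y / lam^2
  dl1 <- r$b; dl2 <- r$A * (1 - r$ek); dl3 <- r$A * ttm * r$k * r$ek
  h11 <- -rowSums(w) * dl1^2 + rowSums(c1) * dl1 - 1 / om[1]
  h22 <- -rowSums(w * dl2^2) + rowSums(c1 * dl2) - 1 / om[2]
  h33 <- -rowSums(w * dl3^2) + rowSums(c1 * dl3 * (1 - r$k * ttm)) - 1 / om[3]
  h12 <- -rowSums(w * dl2) * dl1
  h13 <- -rowSums(w * dl3) * dl1
  h23 <- -rowSums(w * dl2 * dl3) + rowSums(c1 * dl3)
  det3 <- det3x3(-h11, -h12, -h13, -h22, -h23, -h33)
  dets <- det3x3(rowSums(w) * dl1^2 + 1 / om[1],
                 rowSums(w * dl2) * dl1,
                 rowSums(w * dl3) * dl1,
                 rowSums(w * dl2^2) + 1 / om[2],
                 rowSums(w * dl2 * dl3),
                 rowSums(w * dl3^2) + 1 / om[3])
  bad <- !is.finite(det3) | det3 <= 0
  det3[bad] <- dets[bad]
  if (any(!is.finite(det3) | det3 <= 0))
    stop("non-positive Laplace curvature for subject ",
         which(!is.finite(det3) | det3 <= 0)[1])
  ll_i <- g_old + 1.5 * log(2 * pi) - 0.5 * log(det3)
  sum(ll_i)
}

## Closed-form symmetric 3x3 solve A x = g, vectorised over subjects.
solve3 <- function(a11, a12, a13, a22, a23, a33, g1, g2, g3) {
  det <- det3x3(a11, a12, a13, a22, a23, a33)
  x1 <- ((a22 * a33 - a23^2) * g1 + (a13 * a23 - a12 * a33) * g2 +
           (a12 * a23 - a13 * a22) * g3) / det
  x2 <- ((a13 * a23 - a12 * a33) * g1 + (a11 * a33 - a13^2) * g2 +
           (a12 * a13 - a11 * a23) * g3) / det
  x3 <- ((a12 * a23 - a13 * a22) * g1 + (a12 * a13 - a11 * a23) * g2 +
           (a11 * a22 - a12^2) * g3) / det
  list(x1 = x1, x2 = x2, x3 = x3)
}

det3x3 <- function(a11, a12, a13, a22, a23, a33) {
  a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
}
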