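#' Simulate a dataset from a model and study design
#'
#' Draws subject-level random effects from `N(0, Omega)`, assigns covariates
#' (dichotomous: deterministic 0/1 alternation giving an exact half/half split
#' at even N; continuous: standard normal draws) and generates responses from
#' the family's likelihood.  Time-to-event responses are right-censored at the
#' design's censoring horizon.
#'
#' @param model a [model_spec()].
#' @param design a [study_design()].
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return a data frame of class `"nlmem_data"` with columns `id`, `time`,
#'   `covariate`, `dv` and `cens` (censoring indicator, used by the `tte`
#'   family only), one row per observation.
#' @export
#' @examples
#' p <- ppe_preset("tte")
#' d <- simulate_dataset(p$model, p$design, seed = 1)
#' mean(d$cens)  # censored fraction
simulate_dataset <- function(model, design, seed = NULL) {
  stopifnot(inherits(model, "model_spec"), inherits(design, "study_design"))
  N <- design$n_subjects
  with_seed(seed, {
    z <- draw_covariate(model$covariate, N)
    switch(model$family,
      tte = sim_tte(model, design, z),
      binary = sim_binary(model, design, z),
      count = sim_count(model, design, z),
      gaussian_linear = sim_gaussian(model, design, z))
  })
}

draw_covariate <- function(kind, N) {
  if (kind == "dichotomous") rep(c(0, 1), length.out = N) else stats::rnorm(N)
}

nlmem_data <- function(id, time, covariate, dv, cens, model, design) {
  structure(data.frame(id = id, time = time, covariate = covariate,
                       dv = dv, cens = cens),
            family = model$family, n_subjects = design$n_subjects,
            censor_time = design$censor_time,
            class = c("nlmem_data", "data.frame"))
}

sim_tte <- function(model, design, z) {
  th1 <- model$theta[1]; gam <- model$theta[2]; bH <- model$effect
  Tc <- design$censor_time
  if (is.null(Tc)) stop("the tte family needs a censor_time in the design")
  lam <- th1 * exp(bH * z)
  y <- (-log(stats::runif(length(z))))^(1 / gam) / lam  # S(t) = exp(-(lam t)^gam)
  cens <- as.integer(y >= Tc)
  y[cens == 1] <- Tc
  nlmem_data(seq_along(z), y, z, y, cens, model, design)
}

sim_binary <- function(model, design, z) {
  N <- length(z); tt <- design$times; J <- length(tt)
  eta <- mvn_draw(N, model$omega)
  b <- model$theta[1] + eta[, 1]
  a <- (model$theta[2] + eta[, 2]) * (1 - model$effect * z)
  P <- plogis(outer(b, rep(1, J)) + outer(a, tt))
  Y <- matrix(stats::rbinom(N * J, 1, P), N, J)
  nlmem_data(rep(seq_len(N), each = J), rep(tt, N), rep(z, each = J),
             as.vector(t(Y)), 0L, model, design)
}

sim_count <- function(model, design, z) {
  N <- length(z); tt <- design$times; J <- length(tt)
  eta <- mvn_draw(N, model$omega)
  b <- model$theta[1] * exp(eta[, 1])
  A <- model$theta[2] * exp(eta[, 2])
  k <- model$theta[3] * exp(eta[, 3] + model$effect * z)
  lam <- outer(b, rep(1, J)) + A * (1 - exp(-outer(k, tt)))
  Y <- matrix(stats::rpois(N * J, lam), N, J)
  nlmem_data(rep(seq_len(N), each = J), rep(tt, N), rep(z, each = J),
             as.vector(t(Y)), 0L, model, design)
}

sim_gaussian <- function(model, design, z) {
  N <- length(z); tt <- design$times; J <- length(tt)
  th <- model$theta
  eta <- mvn_draw(N, model$omega)
  s0 <- th[1] + eta[, 1]
  slope <- (th[2] + eta[, 2]) * (1 - model$effect * z)
  pbo <- th[3] * (exp(-th[4] * tt) - exp(-th[5] * tt))
  mu <- outer(s0, rep(1, J)) + outer(slope, tt) +
    matrix(pbo, N, J, byrow = TRUE)
  Y <- mu + matrix(stats::rnorm(N * J, 0, sqrt(model$sigma)), N, J)
  nlmem_data(rep(seq_len(N), each = J), rep(tt, N), rep(z, each = J),
             as.vector(t(Y)), 0L, model, design)
}

mvn_draw <- function(N, omega) {
  d <- nrow(omega)
  L <- t(chol(omega + diag(1e-12, d)))
  matrix(stats::rnorm(N * d), N, d) %*% t(L)
}

#' Write / read a simulated dataset as CSV
#'
#' Round-trips the `id,time,covariate,dv,cens` layout used by the engine.
#'
#' @param data an `"nlmem_data"` data frame.
#' @param file path to write to / read from.
#' @param family model family of the stored data (metadata for readers).
#' @return `read_dataset` returns the data frame with the `family` attribute
#'   restored.
#' @export
write_dataset <- function(data, file) {
  utils::write.csv(as.data.frame(data), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file, family) {
  dat <- utils::read.csv(file)
  need <- c("id", "time", "covariate", "dv", "cens")
  if (!all(need %in% names(dat)))
    stop("dataset file must have columns ", paste(need, collapse = ","))
  structure(dat[need], family = family,
            n_subjects = length(unique(dat$id)),
            class = c("nlmem_data", "data.frame"))
}

## Reshape long data into the matrix layout used by the likelihoods.
## All subjects must share the design's observation times (replicated
## reference design); tte data stay in vector form.
nlmem_matrices <- function(data) {
  if (inherits(data, "nlmem_matrices")) return(data)
  ids <- unique(data$id)
  N <- length(ids)
  first <- data$time[data$id == ids[1]]
  J <- length(first)
  if (nrow(data) != N * J)
    stop("unbalanced data: all subjects must share the design times")
  ord <- order(match(data$id, ids), data$time)
  d <- data[ord, ]
  structure(list(Y = matrix(d$dv, N, J, byrow = TRUE),
                 times = first,
                 z = d$covariate[seq(1, N * J, by = J)],
                 N = N, J = J,
                 fingerprint = data_fingerprint(data)),
            class = "nlmem_matrices")
}
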