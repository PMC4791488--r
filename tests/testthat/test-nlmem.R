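test_that("simulated data match closed-form summaries of each family", {
  ## tte: censored fraction in the reference group is the Weibull survivor
  ## function at the horizon, exp(-(0.2 * 10)^2)
  p <- ppe_preset("tte")
  d <- simulate_dataset(p$model, study_design(40000, censor_time = 10),
                        seed = 1)
  z0 <- d$covariate == 0
  expect_lt(abs(mean(d$cens[z0]) - exp(-4)),
            3 * sqrt(exp(-4) * (1 - exp(-4)) / sum(z0)))
  ## binary: mean response at t = 0 is E[expit(theta1 + eta1)], eta1~N(0,0.4),
  ## computed by Gauss-Hermite integration
  pb <- ppe_preset("binary")
  db <- simulate_dataset(pb$model, study_design(20000, times = c(0, 1)),
                         seed = 2)
  gh <- pracma::gaussHermite(40)
  m_th <- sum(gh$w * plogis(-1 + sqrt(2 * 0.4) * gh$x)) / sqrt(pi)
  y0 <- db$dv[db$time == 0]
  expect_lt(abs(mean(y0) - m_th), 3 * sqrt(m_th * (1 - m_th) / length(y0)))
  ## gaussian_linear: the placebo term vanishes at t = 0, so the mean is theta1
  pa <- ppe_preset("alzheimer24")
  da <- simulate_dataset(pa$model, study_design(20000, times = c(0, 0.5)),
                         seed = 3)
  y0 <- da$dv[da$time == 0]
  expect_lt(abs(mean(y0) - 56.4), 3 * sd(y0) / sqrt(length(y0)))
  ## dichotomous covariates split exactly half/half
  expect_identical(sum(d$covariate), nrow(d) / 2)
})

test_that("tte likelihood reproduces a hand-computed Weibull density", {
  p <- ppe_preset("tte")
  d1 <- structure(data.frame(id = 1, time = 1, covariate = 0, dv = 1,
                             cens = 0),
                  class = c("nlmem_data", "data.frame"))
  v <- nlmem_loglik(p$model, c(theta1 = 0.2, gamma = 2, thetaH = 0.4), d1)
  expect_equal(v, log(0.08) - 0.04, tolerance = 1e-10)
  ## censored subject contributes the log survivor function
  d2 <- d1; d2$dv <- 10; d2$cens <- 1
  v2 <- nlmem_loglik(p$model, c(theta1 = 0.2, gamma = 2, thetaH = 0), d2)
  expect_equal(v2, -4, tolerance = 1e-10)
})

test_that("gaussian marginal equals the iid likelihood when Omega vanishes", {
  m0 <- model_spec("gaussian_linear", theta = c(56.4, 4.83, -20, 2.77, 1.73),
                   omega = diag(c(1e-10, 1e-10)), sigma = 1, effect = 0.3)
  dg <- simulate_dataset(m0, study_design(40, times = c(0, 0.5, 1)), seed = 5)
  pars <- c(theta1 = 56.4, theta2 = 4.83, theta3 = -20, theta4 = 2.77,
            theta5 = 1.73, thetaH = 0.3, omega11 = 1e-10, omega22 = 1e-10,
            omega12 = 0, sigma2 = 1)
  tt <- c(0, 0.5, 1)
  pbo <- -20 * (exp(-2.77 * tt) - exp(-1.73 * tt))
  mu <- 56.4 + 4.83 * (1 - 0.3 * dg$covariate) * dg$time + rep(pbo, 40)
  expect_equal(nlmem_loglik(m0, pars, dg),
               sum(dnorm(dg$dv, mu, 1, log = TRUE)), tolerance = 1e-6)
})

test_that("gaussian marginal matches brute-force integration over eta", {
  pa <- ppe_preset("alzheimer24")
  tpa <- nlmem_true_params(pa$model)
  tt <- pa$design$times
  pbo <- -20 * (exp(-2.77 * tt) - exp(-1.73 * tt))
  set.seed(9)
  L <- t(chol(matrix(c(14.3, -1.2, -1.2, 6.1), 2, 2)))
  M <- 2e5
  E <- matrix(rnorm(2 * M), M, 2) %*% t(L)
  for (s in 1:3) {
    da <- simulate_dataset(pa$model, study_design(3, times = tt),
                           seed = 40 + s)
    ll_exact <- nlmem_loglik(pa$model, tpa, da)
    ll_mc <- 0
    se2 <- 0
    for (i in 1:3) {
      yi <- da$dv[da$id == i]
      cz <- 1 - 0.3 * da$covariate[da$id == i][1]
      mu0 <- 56.4 + 4.83 * cz * tt + pbo
      w <- rowSums(vapply(seq_along(tt), function(j)
        dnorm(yi[j], mu0[j] + E[, 1] + E[, 2] * cz * tt[j], sqrt(7.9),
              log = TRUE), numeric(M)))
      mx <- max(w)
      lik <- exp(w - mx)
      ll_mc <- ll_mc + mx + log(mean(lik))
      se2 <- se2 + stats::var(lik) / (M * mean(lik)^2)  # delta-method SE
    }
    expect_lt(abs(ll_exact - ll_mc), 3 * sqrt(se2) + 1e-3)
  }
})

test_that("binary quadrature is exact in the no-random-effect limit and
           stable in the node count", {
  m <- model_spec("binary", theta = c(-1, 4), omega = diag(c(1e-8, 1e-8)),
                  effect = 0.3)
  d <- simulate_dataset(m, study_design(30, times = seq(0, 1, length.out = 20)),
                        seed = 1)
  pars <- c(theta1 = -1, theta2 = 4, thetaH = 0.3, omega1 = 1e-8,
            omega2 = 1e-8)
  lin <- -1 + 4 * (1 - 0.3 * d$covariate) * d$time
  expect_equal(nlmem_loglik(m, pars, d),
               sum(d$dv * lin - log1p(exp(lin))), tolerance = 1e-6)
  pb <- ppe_preset("binary")
  tp <- c(theta1 = -1, theta2 = 4, thetaH = 0.3, omega1 = 0.4, omega2 = 4)
  for (s in 1:5) {
    db <- simulate_dataset(pb$model,
                           study_design(20, times = seq(0, 1, length.out = 20)),
                           seed = 60 + s)
    l7 <- nlmem_loglik(pb$model, tp, db, nodes = 7)
    l15 <- nlmem_loglik(pb$model, tp, db, nodes = 15)
    expect_lt(abs(l7 - l15) / 20, 1e-4)
  }
})

test_that("model fits recover the simulating parameters", {
  ## tte at N = 2000, all three parameters within 3 SE
  p <- ppe_preset("tte")
  d <- simulate_dataset(p$model, study_design(2000, censor_time = 10),
                        seed = 11)
  f <- fit_model(p$model, d)
  se <- nlmem_se(p$model, f, d)
  truth <- c(theta1 = 0.2, gamma = 2, thetaH = 0.4)
  for (nm in names(truth))
    expect_lt(abs(f$theta_hat[[nm]] - truth[[nm]]), 3 * se[[nm]])
  ## gaussian_linear at N = 500: baseline and progression rate
  pa <- ppe_preset("alzheimer24")
  da <- simulate_dataset(pa$model, study_design(500, times = pa$design$times),
                         seed = 12)
  fa <- fit_model(pa$model, da)
  sea <- nlmem_se(pa$model, fa, da)
  expect_lt(abs(fa$theta_hat[["theta1"]] - 56.4), 3 * sea[["theta1"]])
  expect_lt(abs(fa$theta_hat[["theta2"]] - 4.83), 3 * sea[["theta2"]])
})

test_that("the reduced fit never beats the full fit on the same data", {
  p <- ppe_preset("tte")
  for (s in 1:4) {
    d <- simulate_dataset(p$model, study_design(150, censor_time = 10),
                          seed = 70 + s)
    full <- fit_model(p$model, d)
    red <- fit_model(p$model, d, restricted = TRUE)
    expect_identical(red$theta_hat[["thetaH"]], 0)
    expect_lte(red$loglik, full$loglik + 1e-6)
    expect_gte(llr_statistic(full, red), 0)
  }
})

test_that("the LLR statistic checks nesting and data identity", {
  p <- ppe_preset("tte")
  d1 <- simulate_dataset(p$model, study_design(60, censor_time = 10), seed = 1)
  d2 <- simulate_dataset(p$model, study_design(60, censor_time = 10), seed = 2)
  f1 <- fit_model(p$model, d1); r1 <- fit_model(p$model, d1, restricted = TRUE)
  r2 <- fit_model(p$model, d2, restricted = TRUE)
  expect_error(llr_statistic(f1, r2), "same dataset")
  expect_error(llr_statistic(r1, f1), "restricted")
  expect_equal(llr_statistic(f1, r1), 2 * (f1$loglik - r1$loglik))
})

test_that("Wald and LLR statistics are asymptotically close", {
  p <- ppe_preset("tte")
  d <- simulate_dataset(p$model, study_design(2000, censor_time = 10),
                        seed = 11)
  full <- fit_model(p$model, d)
  red <- fit_model(p$model, d, restricted = TRUE)
  w <- wald_statistic(full, p$model, d)
  l <- llr_statistic(full, red)
  expect_lt(abs(w - l) / l, 0.15)
})

test_that("the batched Weibull fitter agrees with the generic optimiser", {
  p <- ppe_preset("tte")
  set.seed(33)
  sim <- ppestim:::sim_tte_batch(5, 120, 0.2, 2, 0.4, 10)
  bf <- ppestim:::fit_tte_batch(sim$y, sim$d, sim$z, full = TRUE)
  br <- ppestim:::fit_tte_batch(sim$y, sim$d, sim$z, full = FALSE)
  for (i in 1:5) {
    df_i <- structure(
      data.frame(id = seq_len(120), time = sim$y[i, ], covariate = sim$z[i, ],
                 dv = sim$y[i, ], cens = 1 - sim$d[i, ]),
      class = c("nlmem_data", "data.frame"))
    f <- fit_model(p$model, df_i)
    r <- fit_model(p$model, df_i, restricted = TRUE)
    expect_equal(bf$loglik[i], f$loglik, tolerance = 1e-6)
    expect_equal(br$loglik[i], r$loglik, tolerance = 1e-6)
    expect_equal(bf$thetaH[i], f$theta_hat[["thetaH"]], tolerance = 1e-4)
    ## batched Wald matches the numeric-Hessian Wald statistic
    wb <- ppestim:::tte_wald_batch(sim$y[i, , drop = FALSE],
                                   sim$d[i, , drop = FALSE],
                                   sim$z[i, , drop = FALSE],
                                   lapply(bf, `[`, i))
    expect_equal(wb, wald_statistic(f, p$model, df_i), tolerance = 1e-3)
  }
})

test_that("count-model likelihood and fit are well behaved at small scale", {
  pc <- ppe_preset("count")
  dc <- simulate_dataset(pc$model,
                         study_design(40, times = seq(0, 1, length.out = 10)),
                         seed = 4)
  tpc <- nlmem_true_params(pc$model)
  ll <- nlmem_loglik(pc$model, tpc, dc)
  expect_true(is.finite(ll))
  ## a Poisson rate doubled everywhere fits these data much worse
  tpc2 <- tpc; tpc2["theta1"] <- 4; tpc2["theta2"] <- 12
  expect_gt(ll, nlmem_loglik(pc$model, tpc2, dc))
  ff <- fit_model(pc$model, dc)
  fr <- fit_model(pc$model, dc, restricted = TRUE)
  expect_gte(llr_statistic(ff, fr), 0)
})

test_that("datasets round-trip through the CSV layout", {
  p <- ppe_preset("tte")
  d <- simulate_dataset(p$model, study_design(25, censor_time = 10), seed = 6)
  f <- tempfile(fileext = ".csv")
  write_dataset(d, f)
  d2 <- read_dataset(f, family = "tte")
  for (col in c("id", "time", "covariate", "dv", "cens"))
    expect_equal(d2[[col]], d[[col]], tolerance = 1e-12)
  expect_identical(attr(d2, "family"), "tte")
})

test_that("ODE-based presets point users to the file-input route", {
  expect_error(ppe_preset("pk"), "supply .* statistics via file")
  expect_error(ppe_preset("pkpd"), "not implemented")
  expect_error(ppe_preset("nonsense"), "unknown preset")
})

test_that("invalid model specifications are rejected at construction", {
  expect_error(model_spec("binary", theta = c(-1, 4),
                          omega = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive semi-definite")
  expect_error(model_spec("binary", theta = c(-1, 4),
                          omega = matrix(c(1, 0.5, 0, 1), 2, 2)), "symmetric")
  expect_error(model_spec("tte", theta = c(0.2, 2), omega = diag(2)),
               "no random effects")
  expect_error(model_spec("binary", theta = 1, omega = diag(2)),
               "2 fixed effects")
  expect_error(study_design(10, times = c(1, 0.5)), "unsorted|strictly")
})
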