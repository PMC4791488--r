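test_that("the non-centrality MLE matches a dense grid-search oracle", {
  set.seed(101)
  cases <- expand.grid(df = c(1, 2, 3), rep = 1:7)
  for (i in seq_len(nrow(cases))) {
    df <- cases$df[i]
    n <- sample(3:50, 1)
    lam_true <- runif(1, 0, 15)
    v <- rchisq(n, df, ncp = lam_true)
    fit <- ppe(v, df = df)
    oracle <- grid_oracle_lambda(v, df)
    expect_equal(fit$lambda, oracle, tolerance = 1e-4,
                 info = sprintf("df=%d n=%d", df, n))
  }
  ## the spec'd worked sample
  fit <- ppe(c(3, 9, 12), df = 1)
  expect_equal(fit$lambda, grid_oracle_lambda(c(3, 9, 12), 1),
               tolerance = 1e-4)
})

test_that("the boundary lambda = 0 is returned exactly when mean <= df", {
  fit <- ppe(c(0.2, 0.9, 1.3), df = 1)
  expect_identical(fit$lambda, 0)
  expect_true(fit$at_boundary)
  set.seed(7)
  for (df in c(1, 2, 3)) {
    for (r in 1:10) {
      v <- rchisq(12, df)   # central draws, mean near df
      fit <- ppe(v, df = df)
      expect_identical(fit$lambda == 0, mean(v) <= df)
      expect_identical(fit$at_boundary, fit$lambda == 0)
    }
  }
})

test_that("lambda is recovered from a large non-central sample", {
  set.seed(42)
  v <- rchisq(10000, 1, ncp = 7.85)
  s <- summary(ppe(v, df = 1))
  expect_lt(abs(s$lambda - 7.85), 3 * s$se_lambda)
  ## sampling SD of lambda-hat shrinks like 1/sqrt(S)
  sds <- sapply(c(100, 400), function(S) {
    X <- matrix(rchisq(300 * S, 1, ncp = 7.85), 300)
    sd(ppestim:::fit_lambda_batch(X, 1))
  })
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.2)
})

test_that("the batched fitter agrees with the scalar fitter", {
  set.seed(9)
  X <- matrix(rchisq(30 * 80, 1, ncp = 6), 30)
  X[1, ] <- rchisq(80, 1)  # include a boundary row
  lam_batch <- ppestim:::fit_lambda_batch(X, 1)
  lam_scalar <- apply(X, 1, function(v) ppestim:::fit_lambda(v, 1)$lambda)
  expect_equal(lam_batch, lam_scalar, tolerance = 1e-6)
})

test_that("power curves scale the fit consistently across study sizes", {
  set.seed(3)
  v <- rchisq(400, 1, ncp = 7.849)
  fit <- ppe(v, df = 1, n_ref = 200)
  curve <- predict(fit, n = c(100, 200, 400))
  ## grid point at n_ref reproduces the single-size estimate exactly
  expect_identical(curve$power[curve$n == 200],
                   power_from_lambda(fit$lambda, 1, 0.05))
  expect_equal(curve$lambda, fit$lambda * c(100, 200, 400) / 200)
  expect_true(all(diff(curve$power) > 0))
  ## close to the theoretical values for lambda ~ 7.85 (Monte Carlo slack)
  expect_equal(curve$power, c(0.51, 0.80, 0.979), tolerance = 0.06)
  ## single-point grid
  one <- predict(fit, n = 200)
  expect_identical(one$power, power_from_lambda(fit$lambda, 1, 0.05))
})

test_that("a boundary fit yields a flat curve at the significance level", {
  fit <- ppe(c(0.1, 0.4, 0.8), df = 1, n_ref = 100, alpha = 0.05)
  curve <- predict(fit, n = c(50, 100, 400))
  expect_equal(curve$power, rep(0.05, 3), tolerance = 1e-12)
})

test_that("curve regeneration from the same seed is bit-identical", {
  set.seed(11)
  v <- rchisq(200, 1, ncp = 6)
  c1 <- ppe_power_curve(v, df = 1, n_ref = 200, sizes = c(100, 200),
                        interval = "bootstrap", B = 150, seed = 77)
  c2 <- ppe_power_curve(v, df = 1, n_ref = 200, sizes = c(100, 200),
                        interval = "bootstrap", B = 150, seed = 77)
  expect_identical(c1, c2)
})

test_that("standard accessors behave like a classed model fit", {
  set.seed(5)
  v <- rchisq(100, 1, ncp = 5)
  fit <- ppe(v, df = 1, n_ref = 150)
  expect_named(coef(fit), "lambda")
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(as.numeric(logLik(fit)),
               sum(dncx2(fit$sample$values, 1, fit$lambda, log = TRUE)))
  expect_output(print(fit), "lambda")
  expect_output(print(summary(fit)), "se\\(lambda\\)")
  sims <- simulate(fit, nsim = 3, seed = 1, s_p = 50)
  expect_identical(dim(sims), c(3L, 50L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1, s_p = 50))
  ci <- confint(fit, B = 120, seed = 2)
  expect_lt(ci[1], fit$lambda)
  expect_gt(ci[2], fit$lambda)
})

test_that("degenerate and invalid inputs are rejected or warned about", {
  expect_warning(ppe(5.2, df = 1), "single statistic")
  expect_error(predict(ppe(c(1, 5, 9), df = 1, n_ref = 100), n = c(100, 50)),
               "strictly increasing")
  fit_no_ref <- ppe(c(1, 5, 9), df = 1)
  expect_error(predict(fit_no_ref, n = 100), "reference study size")
})
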