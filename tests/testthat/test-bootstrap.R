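test_that("a boundary fit propagates to a narrow interval near alpha", {
  set.seed(1)
  v <- runif(200, 0, 1)  # sample mean well below df: lambda-hat = 0
  fit <- ppe(v, df = 1, n_ref = 100)
  expect_true(fit$at_boundary)
  bs <- ppe_bootstrap(fit, B = 200, sizes = c(100, 400), seed = 1)
  ## bootstrap sets are central chi-square; re-estimates pile up at/near 0
  expect_identical(bs$lambda_ci[1], 0)
  expect_lt(bs$lambda_ci[2], 0.4)
  expect_true(all(bs$power_ci_by_size[, "low"] >= 0.05 - 1e-12))
  expect_lt(bs$power_ci_by_size["100", "high"], 0.15)
  ## extrapolating the upper lambda bound to a 4x study widens it, monotonely
  expect_gte(bs$power_ci_by_size["400", "high"],
             bs$power_ci_by_size["100", "high"])
})

test_that("interval width shrinks with the Monte Carlo sample size", {
  set.seed(2)
  v400 <- rchisq(400, 1, ncp = 7.85)
  fit <- ppe(v400, df = 1, n_ref = 200)
  b100 <- ppe_bootstrap(fit, B = 400, s_p = 100, sizes = 200, seed = 5)
  b400 <- ppe_bootstrap(fit, B = 400, s_p = 400, sizes = 200, seed = 5)
  w <- function(b) diff(b$power_ci_by_size[1, ])
  expect_gt(w(b100), w(b400))
  expect_gt(diff(b100$lambda_ci), diff(b400$lambda_ci))
})

test_that("bootstrap results are reproducible and validated", {
  set.seed(3)
  fit <- ppe(rchisq(150, 1, ncp = 6), df = 1, n_ref = 100)
  b1 <- ppe_bootstrap(fit, B = 150, sizes = c(50, 100), seed = 11)
  b2 <- ppe_bootstrap(fit, B = 150, sizes = c(50, 100), seed = 11)
  expect_identical(b1$lambda_draws, b2$lambda_draws)
  expect_identical(b1$power_ci_by_size, b2$power_ci_by_size)
  expect_identical(b1$b, 150L + 0L)
  expect_error(ppe_bootstrap(fit, B = 50), "B >= 100")
  expect_error(ppe_bootstrap(fit, B = 200, s_p = 1), "s_p >= 2")
})

test_that("the CDF band degenerates to a single curve for a single draw", {
  tt <- seq(0, 12, length.out = 50)
  b1 <- ppestim:::ncx2_cdf_band(7.3, df = 1, tt)
  expect_identical(b1$low, b1$high)
  expect_equal(b1$low, pchisq(tt, 1, ncp = 7.3))
  ## with several draws the envelope brackets every member CDF
  draws <- c(5, 6.5, 8)
  be <- ppestim:::ncx2_cdf_band(draws, df = 1, tt)
  for (l in draws) {
    expect_true(all(be$low <= pchisq(tt, 1, ncp = l) + 1e-12))
    expect_true(all(be$high >= pchisq(tt, 1, ncp = l) - 1e-12))
  }
})

test_that("the diagnostic stays quiet for correctly specified samples", {
  for (s in 1:3) {
    set.seed(100 + s)
    fit <- ppe(rchisq(300, 1, ncp = 7.85), df = 1, n_ref = 200)
    d <- ppe_diagnostic(fit, B = 250, seed = s)
    expect_identical(d$flagged, FALSE)
    expect_lt(d$outside_fraction, 0.05)
  }
})

test_that("a point mass at zero (boundary-constrained test) is detected", {
  set.seed(21)
  v <- c(rep(0, 150), rchisq(150, 1, ncp = 7.85))
  fit <- suppressWarnings(ppe(v, df = 1, n_ref = 200))
  expect_warning(d <- ppe_diagnostic(fit, B = 250, seed = 1),
                 "assumption")
  expect_true(d$flagged)
  expect_gt(d$outside_fraction, 0.3)
})

test_that("band construction options behave as documented", {
  set.seed(31)
  fit <- ppe(rchisq(200, 1, ncp = 6), df = 1, n_ref = 100)
  env <- ppe_diagnostic(fit, B = 200, seed = 2, band = "envelope")
  pct <- ppe_diagnostic(fit, B = 200, seed = 2, band = "percentile")
  ## the envelope over retained draws contains the percentile band
  expect_true(all(env$band_low <= pct$band_low + 1e-12))
  expect_true(all(env$band_high >= pct$band_high - 1e-12))
  ## bands are proper CDF curves
  for (d in list(env, pct)) {
    expect_true(all(d$band_low <= d$band_high))
    expect_true(all(diff(d$band_low) >= -1e-12))
    expect_true(all(d$band_low >= 0 & d$band_high <= 1))
  }
  ## strict pointwise comparison is available and more aggressive
  strict <- ppe_diagnostic(fit, B = 200, seed = 2, ecdf_margin = "none")
  expect_gte(strict$outside_fraction, env$outside_fraction)
})
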