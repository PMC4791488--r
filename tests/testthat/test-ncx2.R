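test_that("stable log-density matches the Poisson-mixture definition", {
  ## oracle: log sum_j Poisson(j; ncp/2) * chisq(x; df + 2j), in log space
  mixture_log <- function(x, df, ncp, jmax = 2000 + ncp) {
    j <- 0:jmax
    vapply(x, function(xx) {
      lt <- dpois(j, ncp / 2, log = TRUE) + dchisq(xx, df + 2 * j, log = TRUE)
      m <- max(lt)
      m + log(sum(exp(lt - m)))
    }, numeric(1))
  }
  xs <- c(0.01, 0.5, 1, 3, 10, 40, 120)
  for (df in c(1, 2, 3, 5)) {
    for (ncp in c(0.3, 7.85, 100, 1e4)) {
      expect_equal(dncx2(xs, df, ncp, log = TRUE),
                   mixture_log(xs, df, ncp),
                   tolerance = 1e-7,
                   info = sprintf("df=%g ncp=%g", df, ncp))
    }
  }
  ## agrees with stats::dchisq away from the deep tails (where the built-in
  ## series keeps its accuracy) and at ncp = 0
  xs2 <- c(0.5, 1, 3, 10)
  for (df in c(1, 2, 3)) {
    expect_equal(dncx2(xs2, df, 0, log = TRUE), dchisq(xs2, df, log = TRUE))
    expect_equal(dncx2(xs2, df, 7.85, log = TRUE),
                 dchisq(xs2, df, ncp = 7.85, log = TRUE), tolerance = 1e-8)
  }
  ## remains finite where the density underflows
  expect_true(is.finite(dncx2(0.001, 1, 1e4, log = TRUE)))
})

test_that("density at zero statistics keeps only the ncp-dependent factor", {
  ## df = 2: exact limit exp(-ncp/2)/2
  expect_equal(dncx2(0, 2, 3, log = TRUE), -1.5 - log(2))
  ## df = 1: objective differences across ncp equal -(ncp2 - ncp1)/2,
  ## so zeros pull the MLE toward the boundary without dominating it
  expect_equal(dncx2(0, 1, 5, log = TRUE) - dncx2(0, 1, 1, log = TRUE), -2)
  ## non-log density is floored, never 0
  expect_gt(dncx2(500, 1, 0.1), 0)
})

test_that("critical value inverts the central chi-square CDF", {
  ## independent bisection on pchisq
  bisect_crit <- function(df, alpha) {
    lo <- 0; hi <- 100
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (pchisq(mid, df) < 1 - alpha) lo <- mid else hi <- mid
    }
    mid
  }
  expect_equal(critical_value(1, 0.05), bisect_crit(1, 0.05), tolerance = 1e-6)
  expect_equal(critical_value(1, 0.5), bisect_crit(1, 0.5), tolerance = 1e-6)
  ## df = 2 closed form: -2 log(alpha)
  expect_equal(critical_value(2, 0.05), -2 * log(0.05), tolerance = 1e-10)
})

test_that("power function hits alpha at lambda 0 and is strictly increasing", {
  expect_equal(power_from_lambda(0, 1, 0.05), 0.05, tolerance = 1e-12)
  expect_equal(power_from_lambda(0, 3, 0.17), 0.17, tolerance = 1e-12)
  lam <- seq(0, 60, by = 0.5)
  for (df in c(1, 2, 4)) {
    p <- power_from_lambda(lam, df, 0.05)
    expect_true(all(diff(p) > 0))
  }
  expect_gt(power_from_lambda(200, 1, 0.05), 0.9999)
})

test_that("a non-centrality of ~7.85 gives 80% power for the df=1 test", {
  lam80 <- bisect_lambda_for_power(0.80)      # frozen oracle: 7.8489
  expect_equal(lam80, 7.8489, tolerance = 1e-3)
  expect_equal(power_from_lambda(7.849, 1, 0.05), 0.800, tolerance = 1e-4)
})

test_that("lambda scales linearly with study size", {
  expect_identical(scale_lambda(8, 200, 100), 4)
  expect_identical(scale_lambda(7.85, 200, 200), 7.85)
  expect_equal(scale_lambda(7.85, 200, 300), 11.775)
  expect_equal(scale_lambda(7.85, 200, c(100, 200)), c(3.925, 7.85))
})

test_that("multiplier-derived sizes round up to the next even integer", {
  expect_identical(even_size(110 * c(0.25, 0.5, 0.75, 1, 1.25)),
                   c(28L, 56L, 84L, 110L, 138L))
  expect_identical(even_size(200 * c(0.25, 1.25)), c(50L, 250L))
})
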