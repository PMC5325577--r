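test_that("lag-1 autocorrelation: closed forms and bounds", {
  alt <- rep(c(1, -1), 50)
  expect_lt(abs(lag1_autocorrelation(alt) - (-1)), 0.02)

  set.seed(1)
  expect_lt(abs(lag1_autocorrelation(rnorm(4000))), 0.05)  # 2/sqrt(n) bound

  expect_warning(r <- lag1_autocorrelation(rep(3, 50)), "constant")
  expect_equal(r, 0)
  expect_error(lag1_autocorrelation(1:5), "at least 10")
})

test_that("trend check flags drift and passes white noise", {
  flagged <- vapply(1:100, function(s) {
    set.seed(s)
    trend_check(rnorm(500))$flagged
  }, logical(1))
  expect_gte(mean(!flagged), 0.9)

  set.seed(2)
  n <- 500
  drift <- rnorm(n) + seq(0, 3, length.out = n)  # 3 SDs over the series
  expect_true(trend_check(drift)$flagged)

  tc <- trend_check(rep(1, 100))
  expect_equal(tc$z, 0)
  expect_false(tc$flagged)
  expect_error(trend_check(rnorm(10)), "at least 50")
})

test_that("normality screen uses moment thresholds", {
  set.seed(3)
  expect_false(normality_check(rnorm(4000))$flagged)
  nc <- normality_check(rexp(4000))
  expect_true(nc$flagged)
  expect_gt(nc$skewness, 1)       # exponential skewness ~ 2
  two_point <- rep(c(-1, 1), 200)
  nc2 <- normality_check(two_point)
  expect_true(nc2$flagged)
  expect_lt(nc2$kurtosis, -1.5)   # excess kurtosis of a symmetric two-point
})

test_that("diagnostics are invariant to affine rescaling", {
  set.seed(4)
  x <- cumsum(rnorm(600)) * 0.05 + rnorm(600)
  for (f in list(function(v) 3 * v + 10, function(v) -0.2 * v - 5)) {
    y <- f(x)
    expect_equal(lag1_autocorrelation(y), lag1_autocorrelation(x),
                 tolerance = 1e-10)
    expect_equal(abs(trend_check(y)$z), abs(trend_check(x)$z),
                 tolerance = 1e-6)
    expect_equal(abs(normality_check(y)$skewness),
                 abs(normality_check(x)$skewness), tolerance = 1e-10)
    expect_equal(normality_check(y)$kurtosis, normality_check(x)$kurtosis,
                 tolerance = 1e-10)
  }
})

test_that("convergence report gates on the 0.1 autocorrelation rule", {
  set.seed(5)
  good <- cbind(a = rnorm(3000), b = rnorm(3000))
  rep_good <- convergence_report(good)
  expect_true(rep_good$pass)

  ar <- numeric(500)
  for (i in 2:500) ar[i] <- 0.9 * ar[i - 1] + rnorm(1)
  bad <- cbind(a = rnorm(500), slow = ar)
  rep_bad <- convergence_report(bad)
  expect_false(rep_bad$pass)
  expect_gt(rep_bad$checks$lag1_autocorr[rep_bad$checks$parameter == "slow"],
            0.1)

  path <- withr::local_tempfile(fileext = ".json")
  write_convergence_report(rep_bad, path)
  parsed <- jsonlite::read_json(path)
  expect_false(parsed$pass)
  expect_equal(parsed$ac_threshold, 0.1)
})
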