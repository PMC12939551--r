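test_that("Kaplan-Meier masses match the hand fixture and the product-limit oracle", {
  km <- kaplan_meier(censored_sample(c(1, 2, 3, 4), c(1, 0, 1, 1)))
  expect_equal(km$mass, c(1 / 4, 0, 3 / 8, 3 / 8))
  expect_equal(sum(km$mass), 1)
  # no censoring: empirical cdf
  km2 <- kaplan_meier(censored_sample(c(5, 1, 3), c(1, 1, 1)))
  expect_equal(km2$mass, rep(1 / 3, 3))
  # all censored: zero masses, flagged not fatal
  expect_warning(km3 <- kaplan_meier(censored_sample(c(1, 2), c(0, 0))), "censored")
  expect_equal(km3$mass, c(0, 0))
  # random fixtures against the survival package product-limit estimator
  skip_if_not_installed("survival")
  set.seed(61)
  for (r in 1:10) {
    n <- 30
    x <- rexp(n); tc <- rexp(n, 0.4)
    z <- pmin(x, tc); d <- as.numeric(x <= tc)
    km <- kaplan_meier(censored_sample(z, d))
    fit <- survival::survfit(survival::Surv(z, d) ~ 1)
    surv_at <- stats::approx(fit$time, fit$surv, xout = km$time,
                             method = "constant", yleft = 1, rule = 2)$y
    expect_equal(1 - cumsum(km$mass), surv_at, tolerance = 1e-10)
  }
})

test_that("the censored estimator reduces exactly to the uncensored one without censoring", {
  set.seed(71)
  x <- rexp(40)
  cs <- censored_sample(x, rep(1, 40))
  expect_identical(delta_censored(cs, 1, 0.5, which = 1),
                   delta_hat(x, 1, 0.5, which = 1, grid = "i/N"))
  expect_identical(delta_censored(cs, 2, 0.7, which = 2),
                   delta_hat(x, 2, 0.7, which = 2, grid = "i/N"))
})

test_that("censoring monotonicity: more censoring never increases the total mass", {
  set.seed(81)
  x <- rexp(50)
  tot <- vapply(c(Inf, 3, 1.5, 0.8), function(cap) {
    z <- pmin(x, cap)
    d <- as.numeric(x <= cap)
    if (sum(d) == 0) return(0)
    sum(kaplan_meier(censored_sample(z, d))$mass)
  }, numeric(1))
  expect_true(all(diff(tot) <= 1e-12))
})

test_that("censored variance is non-negative and the statistic behaves under the null", {
  set.seed(91)
  for (r in 1:10) {
    n <- 40
    x <- rexp(n); tc <- rexp(n, 0.3)
    cs <- censored_sample(pmin(x, tc), as.numeric(x <= tc))
    expect_gte(sigma2_censored(cs, 1, 0.5), 0)
  }
  # heavy censoring of the largest observations keeps the statistic finite
  x <- sort(rexp(30))
  d <- c(rep(1, 20), rep(0, 10))
  cs <- censored_sample(x, d)
  expect_true(is.finite(delta_censored(cs, 1, 0.5)))
  expect_lt(sum(kaplan_meier(cs)$mass), 1)
})

test_that("uncensored data give comparable censored and uncensored z-statistics", {
  set.seed(101)
  x <- rexp(300)
  cs <- censored_sample(x, rep(1, 300))
  z_cens <- censored_test(cs, 1, 0.5)$z
  z_unc <- extropy_test(x, 1, 0.5, calibration = "asymptotic")$z
  # plug-in variances differ, but the standardized statistics should be of
  # the same scale and sign on identical data
  expect_equal(sign(z_cens), sign(z_unc))
  expect_lt(abs(z_cens - z_unc), max(1, abs(z_unc)))
})

test_that("the censored test detects aging and errors on degenerate input", {
  set.seed(111)
  rej <- vapply(1:15, function(i) {
    x <- rweibull(150, 2.5)
    tc <- rexp(150, 0.15)
    cs <- censored_sample(pmin(x, tc), as.numeric(x <= tc))
    censored_test(cs, 1, 0.5)$reject
  }, logical(1))
  expect_gte(mean(rej), 0.8)
  expect_error(suppressWarnings(delta_censored(censored_sample(c(1, 2), c(0, 0)), 1, 0.5)),
               "events|degenerate")
})
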