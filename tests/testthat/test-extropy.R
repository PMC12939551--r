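# Riemann-Stieltjes oracle: direct summation of x * J(F_N(x)) over the
# empirical jumps, written independently of the package's vectorized path.
rs_oracle <- function(x, n, b, which, shift = 0L) {
  xs <- sort(x)
  N <- length(xs)
  jf <- if (which == 1) oracle_j1 else oracle_j2
  tot <- 0
  for (i in seq_len(N)) tot <- tot + jf(i / (N + shift), n, b) * xs[i]
  tot / N
}

test_that("L-statistic estimators agree with the Riemann-Stieltjes oracle", {
  set.seed(101)
  for (rep in 1:5) {
    x <- rexp(20 + rep)
    expect_equal(delta_hat(x, 1, 0.5, which = 1), rs_oracle(x, 1, 0.5, 1),
                 tolerance = 1e-12)
    expect_equal(delta_hat(x, 1, 0.7, which = 1), rs_oracle(x, 1, 0.7, 1),
                 tolerance = 1e-12)
    expect_equal(delta_hat(x, 2, 0.7, which = 2), rs_oracle(x, 2, 0.7, 2, shift = 1L),
                 tolerance = 1e-12)
    expect_equal(delta_hat(x, 4, 0.5, which = 2), rs_oracle(x, 4, 0.5, 2, shift = 1L),
                 tolerance = 1e-12)
    # forcing the i/N grid for the second family matches the oracle on it
    expect_equal(delta_hat(x, 2, 0.7, which = 2, grid = "i/N"),
                 rs_oracle(x, 2, 0.7, 2, shift = 0L), tolerance = 1e-12)
  }
})

test_that("estimators are homogeneous of degree 1 and delta* is scale-invariant", {
  set.seed(7)
  x <- rgamma(40, 2)
  for (lam in c(0.01, 7, 1e4)) {
    expect_equal(delta_hat(lam * x, 1, 0.5), lam * delta_hat(x, 1, 0.5))
    expect_equal(delta_star(lam * x, 1, 0.5), delta_star(x, 1, 0.5))
    expect_equal(delta_star(lam * x, 2, 0.7, which = 2),
                 delta_star(x, 2, 0.7, which = 2))
  }
  # constant sample: delta-hat collapses to c * mean weight
  cc <- 3.2
  x <- rep(cc, 12)
  u <- (1:12) / 12
  expect_equal(delta_hat(x, 1, 0.5), cc * mean(j1_weight(u, 1, 0.5)))
})

test_that("delta-hat is near zero on large exponential samples", {
  set.seed(42)
  x <- rexp(1e5)
  expect_lt(abs(delta_star(x, 1, 0.5, which = 1)), 0.01)
  expect_lt(abs(delta_star(x, 2, 0.7, which = 2)), 0.01)
})

test_that("sigma2-hat matches a direct double-loop quadratic form and scales as lambda^2", {
  sigma2_oracle <- function(x, n, b, which) {
    xs <- sort(x)
    N <- length(xs)
    jf <- if (which == 1) oracle_j1 else oracle_j2
    tot <- 0
    for (i in 1:(N - 1)) for (j in 1:(N - 1)) {
      tot <- tot + (min(i / N, j / N) - (i / N) * (j / N)) *
        jf(i / N, n, b) * jf(j / N, n, b) *
        (xs[i + 1] - xs[i]) * (xs[j + 1] - xs[j])
    }
    tot
  }
  set.seed(5)
  x <- rexp(25)
  expect_equal(sigma2_hat(x, 1, 0.5), sigma2_oracle(x, 1, 0.5, 1), tolerance = 1e-12)
  expect_equal(sigma2_hat(x, 2, 0.7, which = 2), sigma2_oracle(x, 2, 0.7, 2),
               tolerance = 1e-12)
  expect_equal(sigma2_hat(3 * x, 1, 0.5), 9 * sigma2_hat(x, 1, 0.5))
  expect_equal(sigma2_hat(rep(2, 10), 1, 0.5), 0)
  # non-negativity across random samples and settings
  for (r in 1:20) {
    y <- rgamma(15, runif(1, 0.5, 3))
    expect_gte(sigma2_hat(y, 1, 0.5), 0)
    expect_gte(sigma2_hat(y, 4, 0.5, which = 2), 0)
  }
})

test_that("extropy_test returns a coherent result object", {
  set.seed(9)
  x <- rweibull(80, 2)
  res <- extropy_test(x, 1, 0.5, calibration = "montecarlo", reps = 1500, seed = 3)
  expect_s3_class(res, "ifra_test")
  expect_equal(res$delta_star, res$delta_hat / mean(x))
  expect_gte(res$sigma2_hat, 0)
  expect_true(res$p_montecarlo >= 0 && res$p_montecarlo <= 1)
  expect_identical(res$reject, unname(res$delta_star > res$critical_value))
  # strongly IFR data should reject on the IFRA side
  expect_true(res$reject)
  # and the decision is invariant under rescaling with the same seed
  res2 <- extropy_test(7 * x, 1, 0.5, calibration = "montecarlo",
                       reps = 1500, seed = 3)
  expect_equal(res2$delta_star, res$delta_star)
  expect_identical(res2$reject, res$reject)
})

test_that("DFRA side rejects for strongly DFR data and errors on degenerate input", {
  set.seed(21)
  rejections <- vapply(1:20, function(i) {
    x <- rweibull(200, 0.5)
    extropy_test(x, 1, 0.5, side = "dfra", calibration = "montecarlo",
                 reps = 800, seed = 100 + i)$reject
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
  expect_error(extropy_test(rep(1, 10), 1, 0.5), "degenerate")
})

test_that("the standardized null statistic is approximately standard normal", {
  # sqrt(N) delta-hat / sigma-hat (const = 1 path) under exponential sampling
  set.seed(33)
  Nn <- 200
  z <- vapply(1:1500, function(i) {
    x <- rexp(Nn)
    sqrt(Nn) * delta_hat(x, 1, 0.5) / sqrt(sigma2_hat(x, 1, 0.5))
  }, numeric(1))
  expect_lt(abs(mean(z)), 0.25)
  expect_gt(sd(z), 0.8)
  expect_lt(sd(z), 1.25)
})

test_that("the standardized statistic is invariant under rescaling of the data", {
  set.seed(44)
  x <- rgamma(70, 2)
  z1 <- extropy_test(x, 1, 0.5, calibration = "asymptotic")$z
  z2 <- extropy_test(1000 * x, 1, 0.5, calibration = "asymptotic")$z
  expect_equal(z1, z2)
  # and equals the raw-statistic standardization
  expect_equal(z1, 2 * sqrt(70) * delta_hat(x, 1, 0.5) / sqrt(sigma2_hat(x, 1, 0.5)))
})
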