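test_that("quantile and cdf are inverse on every family", {
  grid <- c(0.1, 0.5, 1, 2, 5, 10)
  for (fam in c("lfr", "makeham", "gamma", "weibull")) {
    for (th in c(1.2, 2, 3)) {
      m <- lifetime_model(fam, th)
      u <- cdf(m, grid)
      # beyond 1 - 1e-8 the stored probability no longer identifies x in
      # double precision, so the roundtrip is only meaningful below it
      keep <- u < 1 - 1e-8
      expect_equal(quantile(m, u[keep]), grid[keep], tolerance = 1e-7,
                   label = sprintf("%s theta=%g", fam, th))
    }
  }
  m <- lifetime_model("exponential")
  expect_equal(cdf(m, 1), 1 - exp(-1))
})

test_that("family limits recover the exponential", {
  x <- c(0.3, 1, 2.5)
  # LFR theta -> 0
  expect_equal(cdf(lifetime_model("lfr", 1e-10), x), 1 - exp(-x), tolerance = 1e-8)
  # Makeham theta -> 0
  expect_equal(cdf(lifetime_model("makeham", 1e-10), x), 1 - exp(-x), tolerance = 1e-8)
  # Weibull shape 1 is exactly exponential
  expect_equal(cdf(lifetime_model("weibull", 1), x), 1 - exp(-x))
})

test_that("inverse-cdf samplers reproduce the analytic distribution function", {
  for (spec in list(c("weibull", 2), c("lfr", 2), c("makeham", 1.5), c("gamma", 3))) {
    m <- lifetime_model(spec[1], as.numeric(spec[2]))
    x <- rlifetime(m, 1e5, seed = 77)
    ks <- max(abs(ecdf(x)(x) - cdf(m, x)))
    expect_lt(ks, 0.01)
  }
  # seeded draws are reproducible
  expect_identical(rlifetime(lifetime_model("gamma", 2), 10, seed = 4),
                   rlifetime(lifetime_model("gamma", 2), 10, seed = 4))
})

test_that("population deviation measures vanish at the exponential and carry the IFRA sign", {
  m0 <- lifetime_model("exponential")
  for (setting in list(c(1, 0.5, 1), c(1, 0.7, 1), c(2, 0.7, 2), c(4, 0.5, 2))) {
    expect_lt(abs(population_delta(m0, setting[1], setting[2], setting[3])), 1e-8)
  }
  # IFRA members: positive; DFRA members: negative
  expect_gt(population_delta(lifetime_model("weibull", 1.5), 1, 0.5, 1), 0)
  expect_gt(population_delta(lifetime_model("lfr", 2), 1, 0.5, 1), 0)
  expect_gt(population_delta(lifetime_model("gamma", 3), 2, 0.7, 2), 0)
  expect_lt(population_delta(lifetime_model("weibull", 0.5), 1, 0.5, 1), 0)
  expect_lt(population_delta(lifetime_model("gamma", 0.5), 2, 0.7, 2), 0)
})

test_that("empirical delta* is consistent for the LFR(2) population value", {
  m <- lifetime_model("lfr", 2)
  x <- rlifetime(m, 1e4, seed = 123)
  pop_mean <- integrate(function(u) quantile(m, u), 0, 1, rel.tol = 1e-10)$value
  target <- population_delta(m, 1, 0.5, 1) / pop_mean
  est <- delta_star(x, 1, 0.5)
  se <- sqrt(sigma2_hat(x, 1, 0.5) / length(x)) / mean(x)
  expect_lt(abs(est - target), 3 * se)
})

test_that("Weibull minimum extropies match closed forms and direct integrals", {
  # exponential member: CREX(X_{1:1}) = -1/2 int e^{-2x} = -1/4
  expect_equal(weibull_min_extropy(1, 1, 1, "crex"), -0.25, tolerance = 1e-9)
  # general closed form for the survival integral: -Gamma(1+1/beta)/(2 (2 n lambda)^(1/beta))
  for (prm in list(c(1, 1, 1.5), c(2, 0.7, 2.5), c(3, 2, 1))) {
    n <- prm[1]; lam <- prm[2]; beta <- prm[3]
    closed <- -0.5 * gamma(1 + 1 / beta) * (2 * n * lam)^(-1 / beta)
    expect_equal(weibull_min_extropy(n, lam, beta, "crex"), closed, tolerance = 1e-8)
  }
  # CPEX at the exponential member: -1/2 int (1 - (1 - e^{-nx})^2)
  n <- 2
  direct <- -0.5 * integrate(function(x) 1 - (1 - exp(-n * x))^2, 0, Inf)$value
  expect_equal(weibull_min_extropy(n, 1, 1, "cpex"), direct, tolerance = 1e-8)
})

test_that("IFRA inequalities hold for the extropy of the series minimum", {
  # CREX side: EJ(X_{1:n}) <= b EJ(X^b_{1:n});  CPEX side analogously.
  for (beta in c(1, 1.5, 2.5)) {
    for (b in c(0.3, 0.5, 0.9)) {
      for (n in c(1L, 3L)) {
        lhs1 <- weibull_min_extropy(n, 1, beta, "crex")
        rhs1 <- b * weibull_min_extropy(n, 1, beta, "crex", b = b)
        expect_lte(lhs1, rhs1 + 1e-10,
                   label = sprintf("CREX beta=%g b=%g n=%d", beta, b, n))
        lhs2 <- weibull_min_extropy(n, 1, beta, "cpex")
        rhs2 <- b * weibull_min_extropy(n, 1, beta, "cpex", b = b)
        expect_lte(lhs2, rhs2 + 1e-10,
                   label = sprintf("CPEX beta=%g b=%g n=%d", beta, b, n))
        if (beta == 1) {
          # exponential member: the CREX inequality is an equality
          expect_equal(lhs1, rhs1, tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("IFRA inequalities hold for IFR linear-failure-rate minima (quadrature)", {
  # generic integral check using only the model cdf
  min_crex <- function(m, n, b = NULL) {
    e <- if (is.null(b)) 1 else b
    -0.5 * integrate(function(x) (1 - cdf(m, x))^(2 * n * e), 0, Inf,
                     rel.tol = 1e-10)$value
  }
  min_cpex <- function(m, n, b = NULL) {
    e <- if (is.null(b)) 1 else b
    -0.5 * integrate(function(x) 1 - (1 - (1 - cdf(m, x))^n)^(2 * e), 0, Inf,
                     rel.tol = 1e-10)$value
  }
  for (th in c(0.5, 2)) {
    m <- lifetime_model("lfr", th)
    for (b in c(0.3, 0.5, 0.9)) {
      for (n in c(1L, 3L)) {
        expect_lte(min_crex(m, n), b * min_crex(m, n, b) + 1e-10)
        expect_lte(min_cpex(m, n), b * min_cpex(m, n, b) + 1e-10)
      }
    }
  }
})

test_that("model construction rejects invalid parameters", {
  expect_error(lifetime_model("weibull", -1), "positive")
  expect_error(quantile(lifetime_model("gamma", 2), 1), "probs")
  expect_error(cdf(lifetime_model("gamma", 2), -1), "non-negative")
})
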