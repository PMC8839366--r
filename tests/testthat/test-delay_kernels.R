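test_that("density follows the shifted-gamma form with a hard zero at the shift", {
  # unit exponential: f(1) = e^-1; f(0) = 0 by the piecewise convention
  k <- gamma_kernel(1, 0, 0)
  expect_identical(kernel_density(k, 0), 0)
  expect_equal(kernel_density(k, 1), exp(-1), tolerance = 1e-12)
  # shape 1, rate 2 at s = 1: a^2 s e^{-as} = 4 e^-2
  k2 <- gamma_kernel(2, 1, 0)
  expect_equal(kernel_density(k2, 1), 4 * exp(-2), tolerance = 1e-12)
  expect_equal(kernel_density(k2, 1),
               stats::dgamma(1, shape = 2, rate = 2), tolerance = 1e-14)
  # never negative, zero below the shift
  k3 <- gamma_kernel(0.8, 3.2, 4)
  s <- seq(-2, 40, by = 0.25)
  expect_true(all(kernel_density(k3, s) >= 0))
  expect_true(all(kernel_density(k3, s[s <= 4]) == 0))
})

test_that("invalid kernel parameters are rejected", {
  expect_error(gamma_kernel(0, 1, 1), "rate_a")
  expect_error(gamma_kernel(1, -0.1, 1), "shape_m")
  expect_error(gamma_kernel(1, 1, -1), "tau_min")
  expect_error(kernel_density(gamma_kernel(1, 1, 1), Inf), "finite")
})

test_that("closed-form moments match numerical integration of the density", {
  expect_equal(unlist(kernel_moments(gamma_kernel(1, 0, 0))),
               c(mean = 1, variance = 1))
  expect_equal(unlist(kernel_moments(gamma_kernel(2, 3, 5))),
               c(mean = 7, variance = 1))
  k <- gamma_kernel(1.255818, 6.703709, 4.673685)
  mom <- kernel_moments(k)
  num_mean <- stats::integrate(function(s) s * kernel_density(k, s),
                               k$tau_min, k$tau_min + 200,
                               rel.tol = 1e-10)$value
  num_var <- stats::integrate(function(s) (s - mom$mean)^2 * kernel_density(k, s),
                              k$tau_min, k$tau_min + 200,
                              rel.tol = 1e-10)$value
  expect_equal(mom$mean, num_mean, tolerance = 1e-8)
  expect_equal(mom$variance, num_var, tolerance = 1e-7)
})

test_that("Chebyshev truncation bound has the closed form and covers c", {
  expect_equal(truncation_bound(gamma_kernel(1, 0, 0), 0.75)$tau_M, 3)
  expect_equal(truncation_bound(gamma_kernel(2, 3, 5), 0.96)$tau_M, 12)
  # independent arithmetic: tau_min + (m+1)/a + sqrt((m+1)/(a^2 (1-c)))
  a <- 1.255818; m <- 6.703709; tmin <- 4.673685; c <- 0.95
  expected <- tmin + (m + 1) / a + sqrt((m + 1) / (a^2 * (1 - c)))
  rule <- truncation_bound(gamma_kernel(a, m, tmin), c)
  expect_equal(rule$tau_M, expected, tolerance = 1e-12)
  expect_equal(rule$tau_M, 20.69, tolerance = 1e-3)
  expect_error(truncation_bound(gamma_kernel(1, 0, 0), 1), "between 0 and 1")
  expect_error(truncation_bound(gamma_kernel(1, 0, 0), 0), "between 0 and 1")
})

test_that("quadrature weights carry the truncated kernel mass", {
  k <- gamma_kernel(1, 0, 0)
  rule <- truncation_bound(k, 0.75)   # tau_M = 3
  w <- kernel_weights(k, rule, step = 0.001)
  expect_equal(sum(w$weights), 1 - exp(-3), tolerance = 1e-6)
  expect_equal(w$mass, sum(w$weights))
  wr <- kernel_weights(k, rule, step = 0.001, renormalize = TRUE)
  expect_equal(sum(wr$weights), 1, tolerance = 1e-12)
  # continuous-density kernel: trapezoid mass matches the CDF closely
  k2 <- gamma_kernel(2, 4, 1)
  r2 <- truncation_bound(k2, 0.9)
  w2 <- kernel_weights(k2, r2, step = 0.001)
  expect_equal(sum(w2$weights), kernel_cdf(k2, w2$tau_M_grid), tolerance = 1e-6)
  # tau_M rounded up to a step multiple; nodes uniformly spaced
  w3 <- kernel_weights(k2, r2, step = 0.3)
  expect_equal(w3$tau_M_grid / 0.3, round(w3$tau_M_grid / 0.3), tolerance = 1e-9)
  expect_gte(w3$tau_M_grid, r2$tau_M - 1e-9)
  expect_equal(diff(w3$lags), rep(0.3, length(w3$lags) - 1))
  expect_error(kernel_weights(k, rule, step = 5), "resolve|resolution")
})

test_that("a near-degenerate kernel concentrates its weight at the mean lag", {
  k <- gamma_kernel(400, 399, 0)   # mean 1, variance 0.0025
  rule <- truncation_bound(k, 0.95)
  w <- kernel_weights(k, rule, step = 0.01, renormalize = TRUE)
  expect_equal(w$lags[which.max(w$weights)], 1, tolerance = 0.02)
  expect_gt(sum(w$weights[abs(w$lags - 1) < 0.2]), 0.99)
})

test_that("random kernels integrate to one and the bound is conservative", {
  set.seed(42)
  for (i in 1:100) {
    k <- random_kernel()
    total <- stats::integrate(function(s) kernel_density(k, s), k$tau_min, Inf,
                              rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
    for (c in c(0.5, 0.9, 0.99)) {
      rule <- truncation_bound(k, c)
      expect_gte(kernel_cdf(k, rule$tau_M), c)
    }
  }
})

test_that("shifting the kernel translates the density; m = 0 is exponential", {
  set.seed(7)
  for (i in 1:20) {
    a <- stats::runif(1, 0.1, 5); m <- stats::runif(1, 0, 10)
    t0 <- stats::runif(1, 0.5, 8)
    s <- seq(0, 30, by = 0.37)
    expect_equal(kernel_density(gamma_kernel(a, m, t0), s),
                 kernel_density(gamma_kernel(a, m, 0), s - t0),
                 tolerance = 1e-12)
  }
  a <- 1.7
  s <- seq(0.01, 10, by = 0.13)
  expect_equal(kernel_density(gamma_kernel(a, 0, 0), s), a * exp(-a * s),
               tolerance = 1e-12)
})
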