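test_that("state layouts have the family-specific dimensions", {
  expect_length(build_model("mm", list(k1 = 1, k_minus1 = 1, k2 = 1))$species, 4)
  expect_length(build_model("es_discrete", list(kd = 1, tau = 2))$species, 3)
  k <- gamma_kernel(1, 2, 0)
  esi <- build_model("esi_distributed",
                     list(alpha01 = 1, alpha11 = 0.5, beta10 = 0.2,
                          beta11 = 0.1, f01 = k, f11 = k, g10 = k, g11 = k))
  expect_identical(esi$species, c("P01", "P11", "S1", "E", "I1"))
  lat <- build_model("lattice_full",
                     list(N = 1, M = 1, alpha_fwd = matrix(1, 2, 2),
                          alpha_rev = matrix(0.5, 2, 2),
                          beta_fwd = matrix(0.3, 2, 2),
                          beta_rev = matrix(0.2, 2, 2)))
  expect_setequal(lat$species,
                  c("S1", "I1", "R00", "R10", "R01", "R11", "P01", "P11"))
  expect_error(build_model("nope", list()), "unknown model family")
  expect_error(build_model("es_discrete", list(kd = -1, tau = 1)), "nonnegative")
  expect_error(
    build_model("lattice_discrete",
                list(N = 1, M = 1,
                     substrate_channels = list(list(i = 3, j = 1, rate = 1, tau = 1)))),
    "outside the .* lattice")
})

test_that("the instantaneous right-hand side matches direct mass-action arithmetic", {
  m <- build_model("mm", list(k1 = 1, k_minus1 = 0, k2 = 0))
  h <- function(t) c(S = 1, E = 1, C = 0, P = 0)
  expect_equal(evaluate_rhs(m, 0, h), c(S = -1, E = -1, C = 1, P = 0))
  m2 <- build_model("mm", list(k1 = 2, k_minus1 = 3, k2 = 5))
  h2 <- function(t) c(S = 0.4, E = 0.3, C = 0.2, P = 0.1)
  expect_equal(evaluate_rhs(m2, 0, h2),
               c(S = 3 * 0.2 - 2 * 0.4 * 0.3,
                 E = (3 + 5) * 0.2 - 2 * 0.4 * 0.3,
                 C = 2 * 0.4 * 0.3 - 8 * 0.2,
                 P = 5 * 0.2))
})

test_that("the delayed return term vanishes at t = 0 under the standard pre-history", {
  kd <- 0.7; nS0 <- 0.3; nE0 <- 0.2
  m <- build_model("es_discrete", list(kd = kd, tau = 4))
  h <- function(t) if (t < 0) c(0, nE0, 0) else c(nS0, nE0, 0)
  d <- evaluate_rhs(m, 0, h)
  expect_equal(d[["E"]], -kd * nE0 * nS0)
  expect_equal(d[["P"]], 0)
  expect_equal(d[["S"]], -kd * nE0 * nS0)
})

test_that("a zero rate annihilates every derivative", {
  m <- build_model("es_distributed",
                   list(kd = 0, kernel = gamma_kernel(1, 2, 1)))
  h <- function(t) c(1, 1, 0)
  expect_equal(unname(evaluate_rhs(m, 10, h, step = 0.1)), c(0, 0, 0))
})

test_that("distributed rhs equals the quadrature sum over the stored history", {
  kd <- 0.3
  k <- gamma_kernel(2, 1, 0.5)
  m <- build_model("es_distributed", list(kd = kd, kernel = k, confidence = 0.9))
  hist_fun <- function(t) c(exp(-0.1 * abs(t)), 0.5 + 0.01 * t, 0)
  d <- evaluate_rhs(m, 3, hist_fun, step = 0.05)
  w <- kernel_weights(k, truncation_bound(k, 0.9), 0.05)
  conv <- sum(w$weights * vapply(w$lags, function(L) {
    x <- hist_fun(3 - L); x[1] * x[2]
  }, numeric(1)))
  x3 <- hist_fun(3)
  expect_equal(d[["P"]], kd * conv, tolerance = 1e-12)
  expect_equal(d[["E"]], -kd * x3[1] * x3[2] + kd * conv, tolerance = 1e-12)
})

test_that("switching off the inhibitor reduces the ESI model to the ES model", {
  k <- gamma_kernel(1.3, 4, 2)
  kd <- 0.05
  st <- integrator_settings(dt = 0.1)
  esi <- build_model("esi_distributed",
                     list(alpha01 = kd / 2, alpha11 = kd / 2, beta10 = 0,
                          beta11 = 0, f01 = k, f11 = k, g10 = k, g11 = k))
  es <- build_model("es_distributed", list(kd = kd, kernel = k))
  tr_esi <- integrate_model(esi, initial_state(esi, 0.5, 0.04, nI0 = 0), 120, st)
  tr_es <- integrate_model(es, initial_state(es, 0.5, 0.04), 120, st)
  expect_equal(tr_esi$state[, "S1"], unname(tr_es$state[, "S"]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tr_esi$state[, "E"], unname(tr_es$state[, "E"]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tr_esi$state[, "P01"] + tr_esi$state[, "P11"],
               unname(tr_es$state[, "P"]), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("inhibitor concentration never increases in the delayed ESI model", {
  esi <- build_model("esi_discrete",
                     list(alpha01 = 0.3, alpha11 = 0.2, beta10 = 0.4,
                          beta11 = 0.3, tau01 = 2, tau11 = 3, h10 = 1.5, h11 = 2.5))
  tr <- integrate_model(esi, initial_state(esi, 0.6, 0.1, nI0 = 0.2), 80,
                        integrator_settings(dt = 0.05))
  expect_true(all(diff(tr$state[, "I1"]) <= 1e-12))
})

test_that("the full lattice conserves total enzyme across all complexes", {
  lat <- build_model("lattice_full",
                     list(N = 1, M = 1,
                          alpha_fwd = matrix(c(0, 0, 2, 1.5), 2, 2),
                          alpha_rev = matrix(c(0, 0, 0.4, 0.3), 2, 2),
                          beta_fwd = matrix(c(0, 0.8, 0, 0.6), 2, 2),
                          beta_rev = matrix(c(0, 0.2, 0, 0.1), 2, 2)))
  tr <- integrate_model(lat, initial_state(lat, 0.5, 0.1, nI0 = 0.3), 60,
                        integrator_settings(dt = 0.02))
  r_cols <- c("R00", "R10", "R01", "R11")
  tot <- rowSums(tr$state[, r_cols])
  expect_equal(max(abs(tot - 0.1)), 0, tolerance = 1e-9)
  rep <- conservation_report(tr, lat)
  expect_lt(rep$residuals[["enzyme_total"]], 1e-9)
})
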