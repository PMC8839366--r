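test_that("zero delay with constant enzyme gives exponential substrate decay", {
  m <- build_model("es_discrete", list(kd = 1, tau = 0))
  tr <- integrate_model(m, initial_state(m, 1, 1), 5, integrator_settings(dt = 0.01))
  expect_equal(max(abs(tr$state[, "S"] - exp(-tr$time))), 0, tolerance = 1e-4)
  expect_equal(max(abs(tr$state[, "E"] - 1)), 0, tolerance = 1e-10)
  expect_equal(trajectory_at(tr, 5, "S"), exp(-5), tolerance = 1e-4)
})

test_that("all species stay constant when every rate is zero", {
  m <- build_model("es_distributed", list(kd = 0, kernel = gamma_kernel(1, 1, 1)))
  tr <- integrate_model(m, initial_state(m, 0.4, 0.2), 50, integrator_settings(dt = 0.1))
  expect_true(all(tr$state[, "S"] == 0.4))
  expect_true(all(tr$state[, "E"] == 0.2))
  expect_true(all(tr$state[, "P"] == 0))
})

test_that("the integrator converges with at least second order", {
  m <- build_model("es_discrete", list(kd = 0.5, tau = 2))
  ini <- initial_state(m, 1, 0.8)
  ref <- integrate_model(m, ini, 20, integrator_settings(dt = 0.002))
  # the solution has a corner at t = tau where the return flux switches on;
  # the node sample exactly at the corner carries a localized, non-
  # propagating offset, so observed order is measured away from it
  err_at <- function(dt) {
    tr <- integrate_model(m, ini, 20, integrator_settings(dt = dt))
    idx_ref <- match(round(tr$time, 9), round(ref$time, 9))
    keep <- abs(tr$time - 2) > 0.1
    max(abs(tr$state[keep, ] - ref$state[idx_ref[keep], ]))
  }
  e1 <- err_at(0.08); e2 <- err_at(0.04)
  expect_gt(e1 / e2, 3.2)   # observed order >= ~1.7, consistent with order 2
})

test_that("distributed-delay trajectories match the linear-chain oracle", {
  kd <- 0.08; a <- 0.8; m_shape <- 3
  oracle <- chain_trick_oracle(kd, a, m_shape, nS0 = 1, nE0 = 0.6,
                               t_end = 60, dt = 0.02)
  mod <- build_model("es_distributed",
                     list(kd = kd, kernel = gamma_kernel(a, m_shape, 0),
                          confidence = 0.9999))
  tr <- integrate_model(mod, initial_state(mod, 1, 0.6), 60,
                        integrator_settings(dt = 0.02))
  expect_lt(max(abs(tr$state - oracle)), 1e-3)
})

test_that("a narrow kernel approaches the discrete-delay model as variance shrinks", {
  kd <- 0.5
  st <- integrator_settings(dt = 0.01)
  disc <- build_model("es_discrete", list(kd = kd, tau = 1))
  tr_d <- integrate_model(disc, initial_state(disc, 1, 1), 10, st)
  gap <- function(a) {
    k <- gamma_kernel(a, a - 1, 0)  # mean 1, variance 1/a
    mod <- build_model("es_distributed", list(kd = kd, kernel = k))
    tr <- integrate_model(mod, initial_state(mod, 1, 1), 10, st)
    max(abs(tr$state - tr_d$state))
  }
  rng <- diff(range(tr_d$state[, "S"]))
  g400 <- gap(400); g1600 <- gap(1600)
  expect_lt(g400, 0.01 * rng)
  expect_lt(g1600, g400)
})

test_that("delayed lookups beyond the horizon use the constant pre-history", {
  # tau longer than t_end: the return term stays at its pre-history value (0),
  # so E decays exactly like S
  m <- build_model("es_discrete", list(kd = 0.3, tau = 500))
  tr <- integrate_model(m, initial_state(m, 1, 1), 20, integrator_settings(dt = 0.05))
  expect_equal(tr$state[, "E"], tr$state[, "S"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(tr$state[, "P"]) < 1e-12))
})

test_that("conservation residuals are zero for an inert system and bounded otherwise", {
  m0 <- build_model("es_discrete", list(kd = 0, tau = 10))
  tr0 <- integrate_model(m0, initial_state(m0, 0.05, 0.05), 100,
                         integrator_settings(dt = 0.1))
  expect_true(all(conservation_report(tr0, m0)$residuals == 0))

  m1 <- build_model("es_discrete", list(kd = 0.04, tau = 10))
  tr1 <- integrate_model(m1, initial_state(m1, 0.05, 0.05), 500,
                         integrator_settings(dt = 0.05))
  expect_lt(max(conservation_report(tr1, m1)$residuals), 1e-5)
})

test_that("unnormalized weights leak at most the truncation deficit", {
  k <- gamma_kernel(1.255818, 6.703709, 4.673685)
  mod <- build_model("es_distributed", list(kd = 0.04, kernel = k,
                                            confidence = 0.95))
  ini <- initial_state(mod, 0.05, 0.05)
  tr <- integrate_model(mod, ini, 500, integrator_settings(dt = 0.05))
  res <- conservation_report(tr, mod)$residuals
  rule <- truncation_bound(k, 0.95)
  deficit <- (1 - kernel_cdf(k, rule$tau_M)) *
    (0.05 - min(tr$state[, "S"])) +
    1e-5
  expect_lt(res[["enzyme"]], deficit)
  # renormalized weights restore conservation to integrator accuracy
  tr_r <- integrate_model(mod, ini, 500,
                          integrator_settings(dt = 0.05, renormalize = TRUE))
  expect_lt(max(conservation_report(tr_r, mod)$residuals), 1e-5)
})

test_that("a divergent integration raises a named error at the first bad step", {
  m <- build_model("mm", list(k1 = 1e8, k_minus1 = 0, k2 = 0))
  expect_error(
    integrate_model(m, initial_state(m, 1, 1), 10, integrator_settings(dt = 1)),
    class = "delaykin_divergence")
  err <- tryCatch(
    integrate_model(m, initial_state(m, 1, 1), 10, integrator_settings(dt = 1)),
    error = function(e) e)
  expect_match(conditionMessage(err), "step [0-9]+")
})

test_that("a step too coarse for a discrete delay is a settings error", {
  m <- build_model("es_discrete", list(kd = 1, tau = 0.01))
  expect_error(
    integrate_model(m, initial_state(m, 1, 1), 10, integrator_settings(dt = 1)),
    class = "delaykin_settings_error")
})

test_that("conservation reporting rejects a family mismatch", {
  m1 <- build_model("es_discrete", list(kd = 0.1, tau = 1))
  m2 <- build_model("mm", list(k1 = 1, k_minus1 = 1, k2 = 1))
  tr <- integrate_model(m1, initial_state(m1, 1, 1), 5, integrator_settings(dt = 0.05))
  expect_error(conservation_report(tr, m2), "not produced by a model")
})

test_that("oscillation metrics count and size genuine extrema only", {
  t <- seq(0, 10, by = 0.01)
  x <- exp(-t) + 1e-9 * sin(200 * t)       # monotone up to numerical jitter
  om <- oscillation_metrics(x, min_swing = 1e-6)
  expect_identical(om$n_extrema, 0L)
  y <- 1 + exp(-0.3 * t) * cos(3 * t)      # damped oscillation
  om2 <- oscillation_metrics(y, min_swing = 1e-3)
  expect_gt(om2$n_extrema, 3)
  expect_lt(om2$amplitude, 2)
  expect_gt(om2$amplitude, 0.5)
})
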