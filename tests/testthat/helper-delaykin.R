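# Independent linear-chain-trick oracle for the distributed-delay
# enzyme-substrate model with an integer-shape, zero-shift gamma kernel:
# a gamma(m + 1, a) distributed lag equals a cascade of m + 1 first-order
# stages driven by the committed flux u(t) = kd nE nS. Integrated with
# deSolve at tight tolerances; never calls the package's DDE engine.
chain_trick_oracle <- function(kd, a, m, nS0, nE0, t_end, dt) {
  stopifnot(m == round(m))
  rhs <- function(t, y, p) {
    S <- y[1]; E <- y[2]
    z <- y[-(1:3)]
    u <- kd * E * S
    conv <- z[length(z)]
    dz <- a * (c(u, z[-length(z)]) - z)
    list(c(-u, -u + conv, conv, dz))
  }
  y0 <- c(nS0, nE0, 0, rep(0, m + 1))
  out <- deSolve::ode(y0, seq(0, t_end, by = dt), rhs, NULL,
                      method = "ode45", rtol = 1e-10, atol = 1e-12)
  ans <- out[, 2:4]
  colnames(ans) <- c("S", "E", "P")
  ans
}

# small protocol for fast fitting-path tests
tiny_protocol <- function(...) {
  protocol_spec(duration = 200, period = 10, addition_time = 100,
                doses = c(0.3, 1.5), ...)
}

random_kernel <- function() {
  gamma_kernel(rate_a = stats::runif(1, 0.05, 20),
               shape_m = stats::runif(1, 0, 30),
               tau_min = stats::runif(1, 0, 10))
}
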