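# delaykin

Delayed mass-action enzyme kinetics with distributed lifetimes, and
identification of the kinetic and conductivity parameters from
conductometric biosensor time series.

Enzyme biosensors read out catalysis indirectly — here through the
specific conductance of the solution as product accumulates. Classical
Michaelis–Menten modelling requires complex concentrations nobody can
measure; the delayed-mass-action alternative replaces the
enzyme–substrate complex by a stochastic *lifetime* τ, giving delay
differential equations in observable species only. `delaykin` implements
this family of models for modellers and biosensor developers:

* **Delay kernels** — the lifetime is shifted-gamma distributed,
  f(s) = a^(m+1)/Γ(m+1) · (s − τ_min)^m · e^(−a(s − τ_min)) for
  s > τ_min; Chebyshev's inequality supplies the finite truncation bound
  τ_M = E(τ) + √(Var(τ)/(1 − c)) that reduces the infinite history of
  the convolution terms to a finite window.
* **Kinetic models** — the Michaelis–Menten ODE mechanism, the
  discrete-lifetime (Brown-type) and distributed-lifetime
  enzyme–substrate systems, single-substrate single-inhibitor models
  with four delayed channels, general multi-substrate multi-inhibitor
  delayed channel lattices, and the full mass-action complex lattice
  compiled from its reaction schemes. The distributed enzyme–substrate
  core is

  dn_S/dt = −k_d n_E n_S
  dn_E/dt = −k_d n_E n_S + k_d ∫ f(−s) n_E(t+s) n_S(t+s) ds
  dn_P/dt = k_d ∫ f(−s) n_E(t+s) n_S(t+s) ds

* **DDE engine** — a fixed-step, second-order method-of-steps integrator
  (Rcpp core) with grid-aligned quadrature of the distributed terms and
  conservation diagnostics for the bookkeeping identities.
* **Observation model** — Kohlrausch's strong-electrolyte law maps
  product to conductance, κ_pred = Λ_m⁰ n_P − K n_P^(3/2).
* **Identification** — the six parameters Π = (k_d, a, m, τ_min, Λ_m⁰, K)
  are fitted to multi-dose conductivity series by derivative-free
  minimization of the pooled root-sum-square residual under box
  constraints (exact penalty, log-scaled restarted Nelder–Mead).
* **Synthetic experiments** — a generator emulating the dose–response
  protocol (100 samples / 500 s, substrate added at 250 s, doses
  0.1–1.5 mL of 2 mg/mL stock into a BSA–enzyme aggregate) and a
  parameter-recovery harness.

## Worked example

```r
library(delaykin)

## the delay kernel and its finite truncation
k <- gamma_kernel(rate_a = 1.26, shape_m = 6.7, tau_min = 4.67)
k
#> <delay_kernel> shifted gamma: a = 1.26 1/s, m = 6.7, tau_min = 4.67 s
#>   mean delay 10.7811 s, variance 4.85009 s^2
truncation_bound(k, confidence = 0.95)
#> <truncation_rule> c = 0.95, tau_M = 20.6301 s (exact coverage 0.999476)
```

The kernel says complexes live 10.8 s on average (sd ≈ 2.2 s, never less
than 4.67 s); storing 20.6 s of history provably retains ≥ 95 % of the
delay mass (actually 99.95 %).

```r
## simulate one dose of the protocol
model <- build_model("es_distributed", list(kd = 0.04, kernel = k))
ini <- dose_to_initials(protocol_spec(), 0.3)   # nS0 = 0.136, nE0 = 0.0455 mg/mL
tr <- integrate_model(model, initial_state(model, ini$nS0, ini$nE0), 500,
                      integrator_settings(dt = 0.05))
tr
#> <delaykin_trajectory> family 'es_distributed', 10001 nodes, dt = 0.05 s, t in [0, 500] s
#>   final state: S = 0.0568663, E = 0.0443173, P = 0.0783601
signif(conservation_report(tr, model)$residuals, 3)
#>      enzyme substrate_S
#>     4.1e-05     4.1e-05
```

After 500 s, 58 % of the substrate has been converted; the bookkeeping
residual 4.1e-05 is the delay-truncation leak, within its analytic bound
(use `renormalize = TRUE` to remove it).

```r
## synthetic four-dose experiment and parameter identification
truth <- reference_truth()
st <- integrator_settings(dt = 0.25)
series <- generate_series(truth, protocol_spec(), st, noise_sd = 1.7, seed = 1)
fit <- fit_parameters(fit_problem(series, settings = st))
fit
#> <fit_result> J = 23.8364 (rmse 1.66888), 2874 evaluations, NOT converged
#>           kd            a            m      tau_min      lambda0            K
#>   0.07332688   4.24959200  46.80615000   0.48040090 444.63040000  20.37816000
```

The fit drives the residual to the noise floor (rmse 1.67 against noise
sd 1.7). The recovered rate constant lands at 0.073 against a true
0.0404 — a faithful illustration of the k_d–Λ_m⁰ compensation discussed
in the vignette: at these noise levels the data constrain the product of
rate and conductivity scale much more tightly than either factor. The
kernel's *mean* delay is the robustly identified delay quantity.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "delaykin.R", package = "delaykin")` with subcommands
`kernel`, `simulate`, `generate`, `fit`, `recover`.

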