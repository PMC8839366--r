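#' Conductometric experiment protocol
#'
#' Describes the measurement protocol the synthetic generator emulates: a
#' BSA + enzyme aggregate is monitored at a fixed sampling period; at the
#' addition time a substrate dose is pipetted in, and the conductance jump
#' is recorded for the rest of the run. The defaults describe 100 samples
#' at 5 s spacing over 500 s with substrate added at 250 s, doses of 0.1,
#' 0.3, 0.9 and 1.5 mL of a 2 mg/mL substrate stock into 4.0 mL of BSA
#' solution plus 0.1 mL of 2 mg/mL enzyme stock, and a flat instrument
#' baseline.
#'
#' @param duration total run length (s).
#' @param period sampling period (s).
#' @param addition_time substrate addition time (s).
#' @param base_volume BSA solution volume before enzyme/substrate (mL).
#' @param enzyme_stock enzyme stock concentration (mg/mL).
#' @param enzyme_volume enzyme stock volume added (mL).
#' @param substrate_stock substrate stock concentration (mg/mL).
#' @param doses substrate dose volumes (mL).
#' @param baseline pre-addition conductance level (instrument units).
#' @param noise_sd standard deviation of additive Gaussian measurement
#'   noise (instrument units).
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(duration = 500, period = 5, addition_time = 250,
                          base_volume = 4.0, enzyme_stock = 2,
                          enzyme_volume = 0.1, substrate_stock = 2,
                          doses = c(0.1, 0.3, 0.9, 1.5),
                          baseline = 550, noise_sd = 0) {
  stopifnot(duration > 0, period > 0, addition_time > 0,
            addition_time < duration, base_volume > 0, enzyme_stock >= 0,
            enzyme_volume >= 0, substrate_stock > 0, all(doses > 0),
            noise_sd >= 0)
  structure(
    list(duration = duration, period = period, addition_time = addition_time,
         base_volume = base_volume, enzyme_stock = enzyme_stock,
         enzyme_volume = enzyme_volume, substrate_stock = substrate_stock,
         doses = doses, baseline = baseline, noise_sd = noise_sd),
    class = "protocol_spec"
  )
}

#' Initial concentrations from the mixing arithmetic
#'
#' Dilution of the substrate dose and the enzyme stock into the final
#' volume: with pre-addition volume `V0 = base_volume + enzyme_volume`,
#' `nS0 = substrate_stock * v / (V0 + v)` and
#' `nE0 = enzyme_stock * enzyme_volume / (V0 + v)` (mass-concentration
#' units, mg/mL).
#'
#' @param protocol a [protocol_spec()].
#' @param dose_volume substrate dose volume (mL), `> 0`.
#' @return list with `nS0` and `nE0` (mg/mL).
#' @export
dose_to_initials <- function(protocol, dose_volume) {
  stopifnot(inherits(protocol, "protocol_spec"), dose_volume > 0)
  V <- protocol$base_volume + protocol$enzyme_volume + dose_volume
  list(nS0 = protocol$substrate_stock * dose_volume / V,
       nE0 = protocol$enzyme_stock * protocol$enzyme_volume / V)
}

#' Attach model initial concentrations to observed series
#'
#' Computes `nS0`/`nE0` from each series' dose volume through
#' [dose_to_initials()] and stores them on the series, making externally
#' read data fittable.
#'
#' @param series list of [conductivity_series()] with `dose` set.
#' @param protocol a [protocol_spec()].
#' @return the series list with initial concentrations attached.
#' @export
attach_initials <- function(series, protocol) {
  if (inherits(series, "conductivity_series")) series <- list(series)
  lapply(series, function(s) {
    if (is.na(s$dose))
      stop(sprintf("series '%s' has no dose volume; cannot derive initials", s$id),
           call. = FALSE)
    ini <- dose_to_initials(protocol, s$dose)
    s$nS0 <- ini$nS0; s$nE0 <- ini$nE0
    s
  })
}

#' Generate synthetic conductivity series
#'
#' Forward-simulates the distributed-delay enzyme-substrate model for each
#' dose of the protocol and observes it through the Kohlrausch map:
#' pre-addition samples are `baseline + noise`, post-addition samples are
#' `baseline + kappa_pred(nP(t - addition)) + noise`, with i.i.d. additive
#' Gaussian noise.
#'
#' @param truth parameter vector `(kd, a, m, tau_min, lambda0, K)`.
#' @param protocol a [protocol_spec()].
#' @param settings [integrator_settings()] of the forward model.
#' @param confidence kernel truncation confidence level.
#' @param noise_sd Gaussian noise sd; defaults to the protocol's.
#' @param seed optional RNG seed for reproducible noise.
#' @return list of [conductivity_series()], one per dose, each carrying its
#'   `dose`, `nS0` and `nE0`.
#' @export
generate_series <- function(truth, protocol = protocol_spec(),
                            settings = integrator_settings(),
                            confidence = 0.95,
                            noise_sd = protocol$noise_sd, seed = NULL) {
  truth <- as_parameter_vector(truth)
  stopifnot(inherits(protocol, "protocol_spec"), all(truth > 0), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(protocol$period, protocol$duration, by = protocol$period)
  model <- build_model("es_distributed", list(
    kd = truth[["kd"]],
    kernel = gamma_kernel(truth[["a"]], truth[["m"]], truth[["tau_min"]]),
    confidence = confidence))
  horizon <- protocol$duration - protocol$addition_time
  lapply(seq_along(protocol$doses), function(k) {
    v <- protocol$doses[k]
    ini <- dose_to_initials(protocol, v)
    traj <- integrate_model(model, initial_state(model, ini$nS0, ini$nE0),
                            horizon, settings)
    post <- times >= protocol$addition_time
    kappa <- rep(protocol$baseline, length(times))
    nP <- trajectory_at(traj, times[post] - protocol$addition_time, "P")
    kappa[post] <- kappa[post] + kappa_pred(pmax(nP, 0), truth[["lambda0"]],
                                            truth[["K"]])
    if (noise_sd > 0) kappa <- kappa + stats::rnorm(length(kappa), 0, noise_sd)
    conductivity_series(id = sprintf("dose_%g_mL", v), times = times,
                        conductivity = kappa,
                        addition_time = protocol$addition_time,
                        dose = v, nS0 = ini$nS0, nE0 = ini$nE0)
  })
}

#' Noise-free signal range of a protocol under a parameter vector
#'
#' The dynamic range of the noise-free conductance change across all doses
#' (the reference scale for "noise as a fraction of signal range").
#'
#' @inheritParams generate_series
#' @return positive scalar, the largest noise-free conductance change.
#' @export
signal_range <- function(truth, protocol = protocol_spec(),
                         settings = integrator_settings(),
                         confidence = 0.95) {
  nf <- generate_series(truth, protocol, settings, confidence, noise_sd = 0)
  max(vapply(nf, function(s) max(s$conductivity) - min(s$conductivity),
             numeric(1)))
}

#' Parameter-recovery experiment
#'
#' Generates noisy synthetic experiments from a known truth and refits the
#' model for each seed, reporting per-seed estimates and relative errors.
#' The generation and fitting forward models share the same integrator
#' settings, so the recovery error reflects noise and optimizer behavior
#' rather than discretization mismatch. The truth is never modified by the
#' harness.
#'
#' @param truth ground-truth parameter vector.
#' @param protocol a [protocol_spec()].
#' @param seeds integer vector of RNG seeds (one fit per seed).
#' @param noise_frac noise sd as a fraction of the noise-free signal range
#'   (overrides the protocol's absolute `noise_sd` when not `NULL`).
#' @param pi_init,lower,upper fit starting point and bounds.
#' @param settings shared [integrator_settings()] for generation and
#'   fitting.
#' @param confidence kernel truncation confidence level.
#' @param max_iter simplex iteration cap per fit.
#' @return object of class `recovery_report`: `truth`, `estimates`
#'   (seed x parameter matrix), `rel_errors`, `log_errors`
#'   (`|log(est/true)|`, the scale-free error for rate-like parameters),
#'   `median_rel_error`, `converged`, `noise_sd`.
#' @export
recovery_experiment <- function(truth, protocol = protocol_spec(),
                                seeds = 1:5, noise_frac = 0.02,
                                pi_init = default_init(),
                                lower = default_bounds()$lower,
                                upper = default_bounds()$upper,
                                settings = integrator_settings(dt = 0.25),
                                confidence = 0.95, max_iter = 500) {
  truth <- as_parameter_vector(truth)
  stopifnot(length(seeds) >= 1)
  noise_sd <- if (is.null(noise_frac)) protocol$noise_sd else
    noise_frac * signal_range(truth, protocol, settings, confidence)
  est <- matrix(NA_real_, length(seeds), 6,
                dimnames = list(paste0("seed_", seeds), names(truth)))
  conv <- logical(length(seeds)); J <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    series <- generate_series(truth, protocol, settings, confidence,
                              noise_sd = noise_sd, seed = seeds[k])
    prob <- fit_problem(series, pi_init = pi_init, lower = lower,
                        upper = upper, settings = settings,
                        confidence = confidence, max_iter = max_iter)
    fit <- fit_parameters(prob)
    est[k, ] <- fit$pi_opt
    conv[k] <- fit$converged
    J[k] <- fit$J
  }
  rel <- sweep(abs(sweep(est, 2, truth)), 2, truth, "/")
  logerr <- abs(log(sweep(est, 2, truth, "/")))
  structure(
    list(truth = truth, estimates = est, rel_errors = rel,
         log_errors = logerr,
         median_rel_error = apply(rel, 2, stats::median),
         converged = conv, J = J, noise_sd = noise_sd, seeds = seeds),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d seeds, noise sd %.4g\n",
              nrow(x$estimates), x$noise_sd))
  cat("median relative errors:\n")
  print(signif(x$median_rel_error, 4))
  invisible(x)
}
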