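#' Shifted-gamma delay kernel
#'
#' Constructs the probability density of the reaction delay used by the
#' distributed-delay ("delayed mass action") kinetic models. The delay
#' \eqn{\tau} is modelled as \eqn{\tau = \tau_{min} + X} with
#' \eqn{X \sim \Gamma(m + 1, a)} (shape \eqn{m+1}, rate \eqn{a}), i.e.
#' \deqn{f(s) = \frac{a^{m+1}}{\Gamma(m+1)} (s - \tau_{min})^m
#'       e^{-a (s - \tau_{min})}, \quad s > \tau_{min},}
#' and \eqn{f(s) = 0} for \eqn{s \le \tau_{min}}. The shift
#' \eqn{\tau_{min} \ge 0} is the smallest physically possible complex
#' lifetime; \eqn{m} controls the shape and \eqn{a} the rate of the density.
#'
#' @param rate_a positive rate parameter \eqn{a} (1/s).
#' @param shape_m nonnegative shape parameter \eqn{m} (dimensionless).
#' @param tau_min nonnegative minimal delay \eqn{\tau_{min}} (s).
#' @return An object of class `delay_kernel`.
#' @examples
#' k <- gamma_kernel(rate_a = 1.255818, shape_m = 6.703709, tau_min = 4.673685)
#' kernel_moments(k)
#' @export
gamma_kernel <- function(rate_a, shape_m, tau_min = 0) {
  if (!is.numeric(rate_a) || length(rate_a) != 1L || !is.finite(rate_a) || rate_a <= 0)
    stop("`rate_a` must be a single finite positive number", call. = FALSE)
  if (!is.numeric(shape_m) || length(shape_m) != 1L || !is.finite(shape_m) || shape_m < 0)
    stop("`shape_m` must be a single finite nonnegative number", call. = FALSE)
  if (!is.numeric(tau_min) || length(tau_min) != 1L || !is.finite(tau_min) || tau_min < 0)
    stop("`tau_min` must be a single finite nonnegative number", call. = FALSE)
  structure(
    list(rate_a = as.numeric(rate_a), shape_m = as.numeric(shape_m),
         tau_min = as.numeric(tau_min)),
    class = "delay_kernel"
  )
}

#' @export
print.delay_kernel <- function(x, ...) {
  mom <- kernel_moments(x)
  cat(sprintf(
    "<delay_kernel> shifted gamma: a = %g 1/s, m = %g, tau_min = %g s\n",
    x$rate_a, x$shape_m, x$tau_min))
  cat(sprintf("  mean delay %.6g s, variance %.6g s^2\n", mom$mean, mom$variance))
  invisible(x)
}

is_delay_kernel <- function(x) inherits(x, "delay_kernel")

#' Delay density
#'
#' Evaluates the shifted-gamma delay density. By convention the density is
#' exactly 0 at `s <= tau_min`, including at the shift point itself (where
#' the `m = 0` case has a jump to `rate_a` from the right).
#'
#' @param kernel a [gamma_kernel()] object.
#' @param s vector of delays (s); must be finite.
#' @return Density values (1/s), never negative.
#' @export
kernel_density <- function(kernel, s) {
  stopifnot(is_delay_kernel(kernel))
  if (!is.numeric(s) || anyNA(s) || any(!is.finite(s)))
    stop("`s` must be finite numeric", call. = FALSE)
  out <- numeric(length(s))
  pos <- s > kernel$tau_min
  if (any(pos)) {
    out[pos] <- stats::dgamma(s[pos] - kernel$tau_min,
                              shape = kernel$shape_m + 1,
                              rate = kernel$rate_a)
  }
  out
}

#' Delay distribution function
#'
#' Cumulative mass of the delay kernel on `(tau_min, s]`.
#'
#' @inheritParams kernel_density
#' @export
kernel_cdf <- function(kernel, s) {
  stopifnot(is_delay_kernel(kernel))
  stats::pgamma(pmax(s - kernel$tau_min, 0),
                shape = kernel$shape_m + 1, rate = kernel$rate_a)
}

#' Mean and variance of the delay
#'
#' Closed-form moments of the shifted-gamma delay:
#' mean \eqn{\tau_{min} + (m+1)/a}, variance \eqn{(m+1)/a^2}.
#'
#' @inheritParams kernel_density
#' @return A list with elements `mean` (s) and `variance` (s^2).
#' @export
kernel_moments <- function(kernel) {
  stopifnot(is_delay_kernel(kernel))
  list(mean = kernel$tau_min + (kernel$shape_m + 1) / kernel$rate_a,
       variance = (kernel$shape_m + 1) / kernel$rate_a^2)
}

#' Chebyshev truncation bound of the delay distribution
#'
#' The distributed-delay models integrate the history against the delay
#' density over an infinite past. To reduce this to a finite interval the
#' density is truncated at
#' \deqn{\tau_M = E(\tau) + \sqrt{\mathrm{Var}(\tau) / (1 - c)}
#'       = \tau_{min} + \frac{m+1}{a} + \sqrt{\frac{m+1}{a^2 (1-c)}},}
#' which by Chebyshev's inequality carries at least confidence-level `c` of
#' the delay mass (the actual gamma coverage is typically much higher).
#'
#' @inheritParams kernel_density
#' @param confidence confidence level \eqn{c \in (0, 1)}.
#' @return An object of class `truncation_rule` with fields `confidence`,
#'   `tau_M` (s), and `coverage` (the exact gamma CDF at `tau_M`).
#' @export
truncation_bound <- function(kernel, confidence = 0.95) {
  stopifnot(is_delay_kernel(kernel))
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      !is.finite(confidence) || confidence <= 0 || confidence >= 1)
    stop("`confidence` must lie strictly between 0 and 1", call. = FALSE)
  mom <- kernel_moments(kernel)
  tau_M <- mom$mean + sqrt(mom$variance / (1 - confidence))
  structure(
    list(confidence = confidence, tau_M = tau_M,
         coverage = kernel_cdf(kernel, tau_M)),
    class = "truncation_rule"
  )
}

#' @export
print.truncation_rule <- function(x, ...) {
  cat(sprintf("<truncation_rule> c = %g, tau_M = %.6g s (exact coverage %.6f)\n",
              x$confidence, x$tau_M, x$coverage))
  invisible(x)
}

#' Quadrature weights for the distributed-delay integral
#'
#' Discretizes \eqn{\int_{-\tau_M}^{0} f(-s)\, y(t+s)\, ds} on a uniform lag
#' grid aligned with the integrator step, using the composite trapezoid
#' rule. `tau_M` is rounded *up* to an integer multiple of `step` so that
#' quadrature nodes coincide with stored trajectory nodes. By default the
#' weights are the raw trapezoid weights (their sum approximates the kernel
#' mass on `(tau_min, tau_M]`, which is < 1); with `renormalize = TRUE` they
#' are rescaled to sum exactly to 1 so the truncated integral conserves mass.
#'
#' At a node coinciding exactly with `tau_min` the right-limit density value
#' is used for quadrature purposes (relevant only for `shape_m = 0`, where
#' the density jumps); this keeps the composite trapezoid rule second-order
#' accurate across the shift point.
#'
#' @inheritParams kernel_density
#' @param rule a [truncation_bound()] object for this kernel.
#' @param step quadrature/integration step (s), `> 0`.
#' @param renormalize logical; rescale weights to unit sum.
#' @return A list with `lags` (s, nonnegative, `0, step, ..., tau_M_grid`),
#'   `weights` (same length), `tau_M_grid` (the rounded-up bound), and
#'   `mass` (the raw weight sum before any renormalization).
#' @export
kernel_weights <- function(kernel, rule, step, renormalize = FALSE) {
  stopifnot(is_delay_kernel(kernel), inherits(rule, "truncation_rule"))
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("`step` must be a single positive number", call. = FALSE)
  if (step >= rule$tau_M)
    stop(sprintf(
      "step (%g s) does not resolve the delay distribution (tau_M = %g s)",
      step, rule$tau_M), call. = FALSE)
  n <- ceiling(rule$tau_M / step - 1e-9)
  tau_M_grid <- n * step
  lags <- seq(0, n) * step
  f <- kernel_density(kernel, lags)
  if (kernel$shape_m == 0) {
    # right-limit value a at the jump when a node coincides with tau_min
    at_shift <- abs(lags - kernel$tau_min) < 1e-12 * max(1, kernel$tau_min)
    f[at_shift] <- kernel$rate_a
  }
  w <- f * step
  w[c(1L, length(w))] <- w[c(1L, length(w))] / 2
  mass <- sum(w)
  if (renormalize) {
    if (mass <= 0)
      stop("kernel mass on the truncated range is zero; cannot renormalize",
           call. = FALSE)
    w <- w / mass
  }
  list(lags = lags, weights = w, tau_M_grid = tau_M_grid, mass = mass)
}
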