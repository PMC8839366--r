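#' Integrator settings
#'
#' @param dt fixed integration step (s). Discrete delays are snapped to the
#'   nearest integer multiple of `dt`; quadrature nodes of distributed
#'   delays are aligned with the trajectory grid.
#' @param renormalize logical; rescale each kernel's quadrature weights to
#'   unit mass (exact conservation) instead of the raw truncated mass.
#' @return object of class `integrator_settings`.
#' @export
integrator_settings <- function(dt = 0.05, renormalize = FALSE) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  structure(list(dt = as.numeric(dt), renormalize = isTRUE(renormalize)),
            class = "integrator_settings")
}

# Quadrature weights stored only up to `max_lags` grid lags. Histories
# before t = 0 are constant, so kernel mass beyond the stored horizon is
# folded into a scalar tail mass applied to the constant pre-history signal.
# This keeps memory bounded even for kernels whose truncation bound vastly
# exceeds the integration horizon.
weights_capped <- function(kernel, rule, dt, renormalize, max_lags) {
  full_n <- ceiling(rule$tau_M / dt - 1e-9)
  capped <- full_n > max_lags
  H <- as.integer(min(full_n, max_lags))
  lags <- seq(0, H) * dt
  f <- kernel_density(kernel, lags)
  if (kernel$shape_m == 0) {
    at_shift <- abs(lags - kernel$tau_min) < 1e-12 * max(1, kernel$tau_min)
    f[at_shift] <- kernel$rate_a
  }
  w <- f * dt
  w[1L] <- w[1L] / 2
  if (!capped) w[length(w)] <- w[length(w)] / 2
  tail_mass <- if (capped) {
    kernel_cdf(kernel, full_n * dt) - kernel_cdf(kernel, H * dt)
  } else 0
  if (renormalize) {
    total <- sum(w) + tail_mass
    if (total <= 0)
      stop("kernel mass on the truncated range is zero; cannot renormalize",
           call. = FALSE)
    w <- w / total
    tail_mass <- tail_mass / total
  }
  list(weights = w, tail_mass = tail_mass)
}

divergence_error <- function(step, t) {
  stop(structure(
    class = c("delaykin_divergence", "error", "condition"),
    list(message = sprintf(
      "integration diverged: non-finite state first produced at step %d (t = %g s)",
      step, t), call = NULL)))
}

settings_error <- function(msg) {
  stop(structure(
    class = c("delaykin_settings_error", "error", "condition"),
    list(message = msg, call = NULL)))
}

#' Integrate a compiled model
#'
#' Fixed-step explicit Heun (order 2) method-of-steps integration. The
#' solution is stored on the uniform grid `0, dt, ..., K dt`; delayed terms
#' read the stored grid values directly (discrete lags are snapped to grid
#' multiples, distributed-delay quadrature nodes are grid-aligned), and
#' lookups before `t = 0` return the constant pre-history of `init`.
#'
#' @param model a [build_model()] object.
#' @param init an [initial_state()] list (`state0`, `pre`), or any list with
#'   those two named numeric vectors in model species order.
#' @param t_end integration horizon (s); rounded up to a grid multiple.
#' @param settings an [integrator_settings()] object.
#' @return An object of class `delaykin_trajectory`: fields `time`, `state`
#'   (matrix, one column per species), `pre`, `dt`, `family`,
#'   `renormalize`.
#' @examples
#' m <- build_model("es_discrete", list(kd = 1, tau = 0))
#' tr <- integrate_model(m, initial_state(m, nS0 = 1, nE0 = 1), t_end = 5,
#'                       settings = integrator_settings(dt = 0.01))
#' max(abs(tr$state[, "S"] - exp(-tr$time)))
#' @export
integrate_model <- function(model, init, t_end,
                            settings = integrator_settings()) {
  stopifnot(inherits(model, "delaykin_model"),
            inherits(settings, "integrator_settings"))
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) || t_end <= 0)
    stop("`t_end` must be a single positive number", call. = FALSE)
  n <- length(model$species)
  state0 <- unname(init$state0); pre <- unname(init$pre)
  if (length(state0) != n || length(pre) != n)
    stop("`init` does not match the model's state dimension", call. = FALSE)
  dt <- settings$dt
  K <- as.integer(ceiling(t_end / dt - 1e-9))

  nc <- length(model$channels)
  ch_rate <- numeric(nc); ch_f1 <- integer(nc); ch_f2 <- integer(nc)
  ch_type <- integer(nc); ch_lag <- integer(nc); ch_sig <- integer(nc)
  ch_weights <- vector("list", nc); ch_tailw <- vector("list", nc)
  ch_targets <- vector("list", nc); ch_coefs <- vector("list", nc)
  sig_key <- character(0); sig_fac <- list()

  for (c in seq_len(nc)) {
    ch <- model$channels[[c]]
    ch_rate[c] <- ch$rate
    ch_f1[c] <- ch$factors[1] - 1L
    ch_f2[c] <- if (length(ch$factors) > 1) ch$factors[2] - 1L else -1L
    ch_targets[[c]] <- ch$stoich$targets - 1L
    ch_coefs[[c]] <- ch$stoich$coefs
    ch_weights[[c]] <- numeric(0); ch_tailw[[c]] <- numeric(0)
    ch_sig[c] <- -1L
    if (ch$delay$type == "none") {
      ch_type[c] <- 0L
    } else {
      key <- paste(sort(ch$factors), collapse = ",")
      s <- match(key, sig_key)
      if (is.na(s)) {
        sig_key <- c(sig_key, key)
        sig_fac[[length(sig_key)]] <- sort(ch$factors)
        s <- length(sig_key)
      }
      ch_sig[c] <- s - 1L
      if (ch$delay$type == "discrete") {
        ch_type[c] <- 1L
        tau <- ch$delay$tau
        lag <- as.integer(round(tau / dt))
        if (tau > 0 && lag < 1L)
          settings_error(sprintf(
            "dt = %g s cannot resolve the discrete delay tau = %g s; reduce dt",
            dt, tau))
        ch_lag[c] <- lag
      } else {
        ch_type[c] <- 2L
        wc <- weights_capped(ch$delay$kernel, ch$delay$rule, dt,
                             settings$renormalize, max_lags = K)
        ch_weights[[c]] <- wc$weights
        # tailw[L + 1] = sum of weights at lags >= L, plus the tail mass
        ch_tailw[[c]] <- c(rev(cumsum(rev(wc$weights))) + wc$tail_mass,
                           wc$tail_mass)
      }
    }
  }
  ns <- length(sig_key)
  sig_f1 <- integer(ns); sig_f2 <- integer(ns); presig <- numeric(ns)
  for (s in seq_len(ns)) {
    fac <- sig_fac[[s]]
    sig_f1[s] <- fac[1] - 1L
    sig_f2[s] <- if (length(fac) > 1) fac[2] - 1L else -1L
    presig[s] <- prod(pre[fac])
  }

  res <- dde_heun_cpp(state0, K, dt, ch_rate, ch_f1, ch_f2, ch_type,
                      ch_lag, ch_sig, ch_weights, ch_tailw,
                      ch_targets, ch_coefs, sig_f1, sig_f2, presig)
  if (!isTRUE(res$ok)) divergence_error(res$bad_step, res$bad_step * dt)
  X <- res$X
  colnames(X) <- model$species
  structure(
    list(time = seq(0, K) * dt, state = X,
         pre = stats::setNames(pre, model$species), dt = dt,
         family = model$family, renormalize = settings$renormalize),
    class = "delaykin_trajectory"
  )
}

#' @export
print.delaykin_trajectory <- function(x, ...) {
  cat(sprintf("<delaykin_trajectory> family '%s', %d nodes, dt = %g s, t in [0, %g] s\n",
              x$family, length(x$time), x$dt, max(x$time)))
  cat("  final state:", paste(sprintf("%s = %.6g", colnames(x$state),
                                      x$state[nrow(x$state), ]),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.delaykin_trajectory <- function(x, ...) {
  data.frame(time_s = x$time, x$state, check.names = FALSE)
}

#' Sample a trajectory at arbitrary times
#'
#' Linear interpolation of the stored grid solution (exact at grid nodes).
#'
#' @param trajectory a `delaykin_trajectory`.
#' @param times times in `[0, t_end]` (s).
#' @param species species name(s); default all.
#' @return matrix (length(times) x species); a vector for one species.
#' @export
trajectory_at <- function(trajectory, times, species = NULL) {
  stopifnot(inherits(trajectory, "delaykin_trajectory"))
  if (is.null(species)) species <- colnames(trajectory$state)
  if (any(times < -1e-9) || any(times > max(trajectory$time) + 1e-9))
    stop("`times` outside the integrated interval", call. = FALSE)
  out <- vapply(species, function(sp) {
    stats::approx(trajectory$time, trajectory$state[, sp], xout = times,
                  rule = 2)$y
  }, numeric(length(times)))
  if (length(species) == 1L) as.numeric(out) else
    matrix(out, nrow = length(times), dimnames = list(NULL, species))
}

cumtrapz_step <- function(y, dt) dt * (cumsum(y) - (y[1] + y) / 2)

shift_zero <- function(x, lag) {
  if (lag <= 0) return(x)
  if (lag >= length(x)) return(numeric(length(x)))
  c(numeric(lag), x[seq_len(length(x) - lag)])
}

# In-flight reactant mass of one delayed channel: rate * sum_L w_L *
# (CT(t) - CT(t - L dt)), where CT is the cumulative integral of the
# channel's factor-product signal. Mass committed at time u re-emerges a
# kernel-distributed lag later; what has not yet re-emerged is in flight.
channel_inflight <- function(ch, traj, ct) {
  dt <- traj$dt
  if (ch$delay$type == "discrete") {
    lag <- as.integer(round(ch$delay$tau / dt))
    return(ch$rate * (ct - shift_zero(ct, lag)))
  }
  wc <- weights_capped(ch$delay$kernel, ch$delay$rule, dt, traj$renormalize,
                       max_lags = length(ct) - 1L)
  infl <- numeric(length(ct))
  for (L in seq_along(wc$weights) - 1L) {
    w <- wc$weights[L + 1L]
    if (w != 0) infl <- infl + w * (ct - shift_zero(ct, L))
  }
  infl <- infl + wc$tail_mass * ct
  ch$rate * infl
}

#' Conservation diagnostics for a trajectory
#'
#' Evaluates the bookkeeping identities of the model family on a computed
#' trajectory and reports the maximum absolute residual of each.
#'
#' For the delayed enzyme-substrate (-inhibitor) families the identities
#' are: free enzyme plus in-flight enzyme equals the initial enzyme; each
#' substrate plus its products plus in-flight substrate equals the initial
#' substrate; and the linear combination `E - sum(S) - sum(P)` is constant.
#' With unnormalized quadrature weights the enzyme/substrate residuals are
#' bounded by the kernel's truncation deficit rather than by the integrator
#' tolerance. For the Michaelis-Menten family the conserved totals are
#' `S + C + P` and `E + C`; for the full lattice the total enzyme
#' `sum(R[i,j])` is conserved, and inhibitor concentrations in the delayed
#' inhibitor families must be non-increasing.
#'
#' @param trajectory a `delaykin_trajectory` produced from `model`.
#' @param model the model that produced the trajectory.
#' @return list with `residuals` (named max absolute residuals) and
#'   `series` (the residual time series).
#' @export
conservation_report <- function(trajectory, model) {
  stopifnot(inherits(trajectory, "delaykin_trajectory"),
            inherits(model, "delaykin_model"))
  if (!identical(trajectory$family, model$family))
    stop("trajectory was not produced by a model of this family", call. = FALSE)
  X <- trajectory$state; dt <- trajectory$dt
  sp <- colnames(X)
  series <- list()

  if (model$family == "mm") {
    s_tot <- X[, "S"] + X[, "C"] + X[, "P"]
    e_tot <- X[, "E"] + X[, "C"]
    series$substrate_total <- s_tot - s_tot[1]
    series$enzyme_total <- e_tot - e_tot[1]
  } else if (model$family == "lattice_full") {
    r_cols <- grep("^R[0-9]+$", sp, value = TRUE)
    e_tot <- rowSums(X[, r_cols, drop = FALSE])
    series$enzyme_total <- e_tot - e_tot[1]
  } else if (model$family %in% c("es_discrete", "es_distributed",
                                 "esi_discrete", "esi_distributed",
                                 "lattice_discrete", "lattice_distributed")) {
    e_col <- if ("E" %in% sp) "E" else stop("no enzyme species", call. = FALSE)
    delayed <- Filter(function(ch) ch$delay$type != "none", model$channels)
    ct_cache <- list()
    ct_of <- function(fac) {
      key <- paste(sort(fac), collapse = ",")
      if (is.null(ct_cache[[key]])) {
        y <- X[, fac[1]]
        if (length(fac) > 1) y <- y * X[, fac[2]]
        ct_cache[[key]] <<- cumtrapz_step(y, dt)
      }
      ct_cache[[key]]
    }
    # enzyme bookkeeping: every delayed channel returns E
    infl_E <- numeric(nrow(X))
    for (ch in delayed) {
      if (e_col %in% sp[ch$stoich$targets[ch$stoich$coefs > 0]])
        infl_E <- infl_E + channel_inflight(ch, trajectory, ct_of(ch$factors))
    }
    series$enzyme <- X[, e_col] + infl_E - X[1, e_col]
    # substrate bookkeeping per substrate species
    s_cols <- grep("^S[0-9]*$", sp, value = TRUE)
    for (s in s_cols) {
      infl <- numeric(nrow(X)); prod_sum <- numeric(nrow(X))
      for (ch in delayed) {
        if (!(match(s, sp) %in% ch$factors)) next
        infl <- infl + channel_inflight(ch, trajectory, ct_of(ch$factors))
        p_t <- sp[ch$stoich$targets[ch$stoich$coefs > 0]]
        p_t <- grep("^P", p_t, value = TRUE)
        if (length(p_t)) prod_sum <- prod_sum + rowSums(X[, p_t, drop = FALSE])
      }
      series[[paste0("substrate_", s)]] <- X[, s] + prod_sum + infl - X[1, s]
    }
    i_cols <- grep("^I[0-9]+$", sp, value = TRUE)
    for (ic in i_cols)
      series[[paste0("monotone_", ic)]] <- pmax(c(0, diff(X[, ic])), 0)
  } else {
    stop(sprintf("no conservation invariants registered for family '%s'",
                 model$family), call. = FALSE)
  }
  list(residuals = vapply(series, function(r) max(abs(r)), numeric(1)),
       series = series)
}

#' Oscillation metrics of a species trajectory
#'
#' Counts interior local extrema of a series after pruning turning points
#' whose peak-to-trough swing is below `min_swing` (numerical jitter), and
#' reports the largest swing between consecutive surviving interior
#' extrema. A non-oscillatory dip-and-recover enzyme response has one
#' interior extremum and zero oscillation amplitude; damped oscillations
#' add extrema pairs.
#'
#' @param x numeric series (e.g. `trajectory$state[, "E"]`).
#' @param min_swing absolute swing below which turning points are pruned.
#' @return list with `n_extrema` (interior turning points) and `amplitude`
#'   (largest swing between consecutive interior extrema; 0 if fewer than
#'   two).
#' @export
oscillation_metrics <- function(x, min_swing = 0) {
  stopifnot(is.numeric(x), length(x) >= 2)
  dx <- diff(x); nz <- which(dx != 0)
  idx <- integer(0)
  if (length(nz) >= 2) {
    s <- sign(dx[nz])
    chg <- which(s[-1] != s[-length(s)])
    idx <- nz[chg] + 1L
  }
  vals <- c(x[1], x[idx], x[length(x)])
  repeat {
    if (length(vals) <= 2) break
    sw <- abs(diff(vals))
    k <- which.min(sw)
    if (sw[k] >= min_swing) break
    if (k == 1) {
      vals <- vals[-2]
    } else if (k == length(sw)) {
      vals <- vals[-(length(vals) - 1L)]
    } else {
      vals <- vals[-c(k, k + 1L)]
    }
  }
  n_ext <- length(vals) - 2L
  interior <- vals[-c(1, length(vals))]
  amp <- if (length(interior) >= 2) max(abs(diff(interior))) else 0
  list(n_extrema = n_ext, amplitude = amp)
}
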