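#' @useDynLib delaykin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# A compiled model is a state layout plus a list of mass-action reaction
# channels. Each channel is
#   list(rate, factors = <species indices, length 1 or 2>,
#        delay = list(type = "none" | "discrete" | "kernel", ...),
#        stoich = list(targets = <indices>, coefs = <signed numbers>))
# Instantaneous consumption and delayed return of one physical reaction are
# separate channels sharing the same rate and factor set.

delay_none <- function() list(type = "none")
delay_discrete <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("discrete delay `tau` must be a single nonnegative number", call. = FALSE)
  list(type = "discrete", tau = as.numeric(tau))
}
delay_kernel_spec <- function(kernel, confidence = 0.95) {
  stopifnot(is_delay_kernel(kernel))
  rule <- truncation_bound(kernel, confidence)
  list(type = "kernel", kernel = kernel, confidence = confidence, rule = rule)
}

new_channel <- function(rate, factors, delay, targets, coefs) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("reaction rates must be single finite nonnegative numbers", call. = FALSE)
  list(rate = as.numeric(rate), factors = as.integer(factors), delay = delay,
       stoich = list(targets = as.integer(targets), coefs = as.numeric(coefs)))
}

new_model <- function(family, species, channels, meta = list()) {
  for (ch in channels) {
    if (any(ch$factors < 1L | ch$factors > length(species)) ||
        any(ch$stoich$targets < 1L | ch$stoich$targets > length(species)))
      stop("channel references a species outside the state layout", call. = FALSE)
  }
  structure(
    list(family = family, species = species, channels = channels, meta = meta),
    class = "delaykin_model"
  )
}

#' @export
print.delaykin_model <- function(x, ...) {
  nd <- sum(vapply(x$channels, function(ch) ch$delay$type != "none", logical(1)))
  cat(sprintf("<delaykin_model> family '%s': %d species (%s), %d channels (%d delayed)\n",
              x$family, length(x$species), paste(x$species, collapse = ", "),
              length(x$channels), nd))
  invisible(x)
}

#' Maximum delay horizon of a model
#'
#' The largest lag any channel of the model can look back: the discrete
#' delay or the Chebyshev truncation bound \eqn{\tau_M} of the kernel.
#'
#' @param model a compiled model from [build_model()].
#' @return horizon in seconds (0 for purely instantaneous models).
#' @export
delay_horizon <- function(model) {
  stopifnot(inherits(model, "delaykin_model"))
  h <- 0
  for (ch in model$channels) {
    if (ch$delay$type == "discrete") h <- max(h, ch$delay$tau)
    if (ch$delay$type == "kernel") h <- max(h, ch$delay$rule$tau_M)
  }
  h
}

need_scalar <- function(params, key, default = NULL) {
  v <- params[[key]]
  if (is.null(v)) {
    if (!is.null(default)) return(default)
    stop(sprintf("missing required parameter `%s`", key), call. = FALSE)
  }
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop(sprintf("parameter `%s` must be a single finite number", key), call. = FALSE)
  as.numeric(v)
}

build_mm <- function(params) {
  k1 <- need_scalar(params, "k1"); km1 <- need_scalar(params, "k_minus1")
  k2 <- need_scalar(params, "k2")
  sp <- c("S", "E", "C", "P")
  ch <- list(
    new_channel(k1, c(2L, 1L), delay_none(), c(1L, 2L, 3L), c(-1, -1, 1)),
    new_channel(km1, 3L, delay_none(), c(3L, 1L, 2L), c(-1, 1, 1)),
    new_channel(k2, 3L, delay_none(), c(3L, 2L, 4L), c(-1, 1, 1))
  )
  new_model("mm", sp, ch)
}

es_delay_spec <- function(params, family) {
  if (family == "es_discrete") {
    delay_discrete(need_scalar(params, "tau"))
  } else {
    if (!is_delay_kernel(params$kernel))
      stop("`kernel` must be a gamma_kernel() for the distributed family", call. = FALSE)
    delay_kernel_spec(params$kernel, need_scalar(params, "confidence", 0.95))
  }
}

build_es <- function(params, family) {
  kd <- need_scalar(params, "kd")
  dl <- es_delay_spec(params, family)
  sp <- c("S", "E", "P")
  ch <- list(
    new_channel(kd, c(2L, 1L), delay_none(), c(1L, 2L), c(-1, -1)),
    new_channel(kd, c(2L, 1L), dl, c(2L, 3L), c(1, 1))
  )
  new_model(family, sp, ch)
}

one_lattice_delay <- function(spec, confidence) {
  if (!is.null(spec$tau)) {
    delay_discrete(spec$tau)
  } else if (is_delay_kernel(spec$kernel)) {
    delay_kernel_spec(spec$kernel, confidence)
  } else {
    stop("each channel needs either `tau` (discrete) or `kernel` (distributed)",
         call. = FALSE)
  }
}

# Generalized delayed lattice model: explicit substrate channels
# (i, j, rate, delay) produce P_{i,j} and return E after the channel delay;
# inhibitor channels consume I_i and return E after the channel delay.
build_lattice_delayed <- function(params, family) {
  N <- as.integer(need_scalar(params, "N"))
  M <- as.integer(need_scalar(params, "M"))
  if (N < 0 || M < 1) stop("need N >= 0 inhibitors and M >= 1 substrates", call. = FALSE)
  subs <- params$substrate_channels
  inhs <- if (is.null(params$inhibitor_channels)) list() else params$inhibitor_channels
  if (is.null(subs) || !length(subs))
    stop("at least one substrate channel is required", call. = FALSE)
  confidence <- need_scalar(params, "confidence", 0.95)

  check_idx <- function(i, j, what) {
    if (i < 0 || i > N || j < 0 || j > M)
      stop(sprintf("%s channel index (i=%d, j=%d) outside the (N=%d, M=%d) lattice",
                   what, i, j, N, M), call. = FALSE)
  }
  pnames <- vapply(subs, function(s) sprintf("P%d%d", s$i, s$j), character(1))
  if (anyDuplicated(pnames))
    stop("duplicate substrate channel indices", call. = FALSE)
  sp <- c(pnames, paste0("S", seq_len(M)), "E",
          if (N > 0) paste0("I", seq_len(N)) else character(0))
  iS <- function(j) length(pnames) + j
  iE <- length(pnames) + M + 1L
  iI <- function(i) length(pnames) + M + 1L + i

  ch <- list()
  for (k in seq_along(subs)) {
    s <- subs[[k]]
    check_idx(s$i, s$j, "substrate")
    if (s$j < 1) stop("substrate channels need j >= 1", call. = FALSE)
    dl <- one_lattice_delay(s, confidence)
    rate <- need_scalar(s, "rate")
    ch <- c(ch, list(
      new_channel(rate, c(iE, iS(s$j)), delay_none(), c(iS(s$j), iE), c(-1, -1)),
      new_channel(rate, c(iE, iS(s$j)), dl, c(iE, k), c(1, 1))
    ))
  }
  seen <- character(0)
  for (s in inhs) {
    check_idx(s$i, s$j, "inhibitor")
    if (s$i < 1) stop("inhibitor channels need i >= 1", call. = FALSE)
    key <- sprintf("%d,%d", s$i, s$j)
    if (key %in% seen) stop("duplicate inhibitor channel indices", call. = FALSE)
    seen <- c(seen, key)
    dl <- one_lattice_delay(s, confidence)
    rate <- need_scalar(s, "rate")
    ch <- c(ch, list(
      new_channel(rate, c(iI(s$i), iE), delay_none(), c(iI(s$i), iE), c(-1, -1)),
      new_channel(rate, c(iI(s$i), iE), dl, iE, 1)
    ))
  }
  new_model(family, sp, ch, meta = list(N = N, M = M, products = pnames))
}

# The single-substrate single-inhibitor models are the delayed lattice with
# the fixed channel set {(0,1), (1,1)} for the substrate and
# {(1,0), (1,1)} for the inhibitor.
build_esi <- function(params, family) {
  if (family == "esi_discrete") {
    subs <- list(list(i = 0L, j = 1L, rate = need_scalar(params, "alpha01"),
                      tau = need_scalar(params, "tau01")),
                 list(i = 1L, j = 1L, rate = need_scalar(params, "alpha11"),
                      tau = need_scalar(params, "tau11")))
    inhs <- list(list(i = 1L, j = 0L, rate = need_scalar(params, "beta10"),
                      tau = need_scalar(params, "h10")),
                 list(i = 1L, j = 1L, rate = need_scalar(params, "beta11"),
                      tau = need_scalar(params, "h11")))
  } else {
    for (k in c("f01", "f11", "g10", "g11"))
      if (!is_delay_kernel(params[[k]]))
        stop(sprintf("`%s` must be a gamma_kernel()", k), call. = FALSE)
    subs <- list(list(i = 0L, j = 1L, rate = need_scalar(params, "alpha01"),
                      kernel = params$f01),
                 list(i = 1L, j = 1L, rate = need_scalar(params, "alpha11"),
                      kernel = params$f11))
    inhs <- list(list(i = 1L, j = 0L, rate = need_scalar(params, "beta10"),
                      kernel = params$g10),
                 list(i = 1L, j = 1L, rate = need_scalar(params, "beta11"),
                      kernel = params$g11))
  }
  m <- build_lattice_delayed(
    list(N = 1, M = 1, substrate_channels = subs, inhibitor_channels = inhs,
         confidence = need_scalar(params, "confidence", 0.95)),
    family)
  m
}

mat_entry <- function(mat, i, j, default = 0) {
  if (is.null(mat)) return(default)
  if (i + 1 > nrow(mat) || j + 1 > ncol(mat)) return(default)
  v <- mat[i + 1, j + 1]
  if (is.na(v)) default else v
}

# Full lattice mass-action network compiled from the reaction schemes:
#   R_{i,j-1} + S_j <-> R_{i,j}   (alpha_fwd[i,j] / alpha_rev[i,j])
#   R_{i-1,j} + I_i <-> R_{i,j}   (beta_fwd[i,j] / beta_rev[i,j])
#   R_{i,j} -> E + P_{i,j}        (gamma[i,j]),  E = R_{0,0}
# Rate matrices are (N+1) x (M+1), row = i + 1, col = j + 1; entries at
# positions where the reaction does not exist are ignored.
build_lattice_full <- function(params) {
  N <- as.integer(need_scalar(params, "N"))
  M <- as.integer(need_scalar(params, "M"))
  if (N < 0 || M < 1) stop("need N >= 0 inhibitors and M >= 1 substrates", call. = FALSE)
  af <- params$alpha_fwd; ar <- params$alpha_rev
  bf <- params$beta_fwd; br <- params$beta_rev
  gm <- params$gamma
  if (is.null(gm)) {
    gm <- matrix(0, N + 1, M + 1)
    gm[, -1] <- 1   # default: every substrate-bearing complex is catalytic
  }
  for (nm in list(af, ar, bf, br, gm)) {
    if (!is.null(nm) && (!is.matrix(nm) || any(nm[is.finite(nm)] < 0)))
      stop("rate matrices must be numeric matrices with nonnegative entries",
           call. = FALSE)
  }
  sp_S <- paste0("S", seq_len(M))
  sp_I <- if (N > 0) paste0("I", seq_len(N)) else character(0)
  grid <- expand.grid(i = 0:N, j = 0:M)      # i fastest: R00, R10, ..., R01, ...
  sp_R <- sprintf("R%d%d", grid$i, grid$j)
  cat_idx <- which(mapply(function(i, j) mat_entry(gm, i, j) > 0, grid$i, grid$j))
  sp_P <- sprintf("P%d%d", grid$i[cat_idx], grid$j[cat_idx])
  sp <- c(sp_S, sp_I, sp_R, sp_P)
  iS <- function(j) j
  iI <- function(i) M + i
  iR <- function(i, j) M + N + j * (N + 1L) + i + 1L
  iP <- function(k) M + N + length(sp_R) + k

  ch <- list()
  for (i in 0:N) for (j in seq_len(M)) {
    a <- mat_entry(af, i, j)
    if (a > 0)
      ch <- c(ch, list(new_channel(a, c(iR(i, j - 1L), iS(j)), delay_none(),
                                   c(iR(i, j - 1L), iS(j), iR(i, j)), c(-1, -1, 1))))
    arv <- mat_entry(ar, i, j)
    if (arv > 0)
      ch <- c(ch, list(new_channel(arv, iR(i, j), delay_none(),
                                   c(iR(i, j), iR(i, j - 1L), iS(j)), c(-1, 1, 1))))
  }
  if (N > 0) for (i in seq_len(N)) for (j in 0:M) {
    b <- mat_entry(bf, i, j)
    if (b > 0)
      ch <- c(ch, list(new_channel(b, c(iR(i - 1L, j), iI(i)), delay_none(),
                                   c(iR(i - 1L, j), iI(i), iR(i, j)), c(-1, -1, 1))))
    brv <- mat_entry(br, i, j)
    if (brv > 0)
      ch <- c(ch, list(new_channel(brv, iR(i, j), delay_none(),
                                   c(iR(i, j), iR(i - 1L, j), iI(i)), c(-1, 1, 1))))
  }
  for (k in seq_along(cat_idx)) {
    i <- grid$i[cat_idx[k]]; j <- grid$j[cat_idx[k]]
    g <- mat_entry(gm, i, j)
    ch <- c(ch, list(new_channel(g, iR(i, j), delay_none(),
                                 c(iR(i, j), iR(0L, 0L), iP(k)), c(-1, 1, 1))))
  }
  new_model("lattice_full", sp, ch,
            meta = list(N = N, M = M, complexes = sp_R, products = sp_P))
}

#' Build a compiled kinetic model
#'
#' Compiles one of the enzyme-kinetic model families into a reaction-channel
#' form that the integrator and the right-hand-side evaluator consume.
#'
#' Families:
#' \describe{
#'   \item{`mm`}{Classical irreversible one-complex Michaelis-Menten ODE
#'     mechanism. `params`: `k1`, `k_minus1`, `k2`. Species `S, E, C, P`.}
#'   \item{`es_discrete`}{Brown-type enzyme-substrate model: the complex has
#'     a fixed lifetime `tau` before releasing enzyme and product.
#'     `params`: `kd`, `tau`. Species `S, E, P`.}
#'   \item{`es_distributed`}{Same mechanism with a gamma-distributed complex
#'     lifetime. `params`: `kd`, `kernel` (a [gamma_kernel()]), optional
#'     `confidence` (truncation level, default 0.95).}
#'   \item{`esi_discrete` / `esi_distributed`}{Single-substrate
#'     single-inhibitor model with two substrate channels (through the ES
#'     and the EIS complex) and two inhibitor channels. Discrete `params`:
#'     `alpha01, alpha11, beta10, beta11, tau01, tau11, h10, h11`;
#'     distributed: rates plus kernels `f01, f11, g10, g11` and optional
#'     `confidence`. Species `P01, P11, S1, E, I1`.}
#'   \item{`lattice_discrete` / `lattice_distributed`}{General
#'     multi-substrate multi-inhibitor delayed model with explicit channel
#'     lists: `params$substrate_channels` / `params$inhibitor_channels`,
#'     each element `list(i =, j =, rate =, tau = | kernel =)`, plus `N`,
#'     `M` and optional `confidence`.}
#'   \item{`lattice_full`}{Full mass-action lattice of enzyme-substrate-
#'     inhibitor complexes `R[i,j]` (with `E = R[0,0]`) compiled from the
#'     binding/unbinding/catalysis reaction schemes. `params`: `N`, `M` and
#'     rate matrices `alpha_fwd`, `alpha_rev`, `beta_fwd`, `beta_rev`,
#'     `gamma` (`(N+1) x (M+1)`, row `i+1`, column `j+1`; by default every
#'     substrate-bearing complex is catalytic and inhibitor-only complexes
#'     are not).}
#' }
#'
#' @param family model family tag (see Details).
#' @param params named list of family-specific parameters.
#' @return An object of class `delaykin_model`.
#' @examples
#' build_model("es_distributed",
#'             list(kd = 0.04, kernel = gamma_kernel(1.26, 6.7, 4.67)))
#' @export
build_model <- function(family, params = list()) {
  if (!is.list(params)) stop("`params` must be a list", call. = FALSE)
  switch(
    family,
    mm = build_mm(params),
    es_discrete = build_es(params, "es_discrete"),
    es_distributed = build_es(params, "es_distributed"),
    esi_discrete = build_esi(params, "esi_discrete"),
    esi_distributed = build_esi(params, "esi_distributed"),
    lattice_discrete = build_lattice_delayed(params, "lattice_discrete"),
    lattice_distributed = build_lattice_delayed(params, "lattice_distributed"),
    lattice_full = build_lattice_full(params),
    stop(sprintf("unknown model family '%s'", family), call. = FALSE)
  )
}

#' Initial state and pre-history for a model
#'
#' Builds the standard initial condition: substrates (and inhibitors) are
#' zero on the pre-history `[-tau_M, 0)` and jump to their dose values at
#' `t = 0`; free enzyme is constant at `nE0` on the whole pre-history;
#' products and complexes start at zero. For the full lattice model the
#' free-enzyme pool is the complex `R00`.
#'
#' @param model a compiled model.
#' @param nS0 initial substrate concentration(s), recycled over substrates.
#' @param nE0 initial enzyme concentration.
#' @param nI0 initial inhibitor concentration(s), recycled over inhibitors
#'   (ignored by models without inhibitors).
#' @return list with named vectors `state0` (right-limit state at `t = 0`)
#'   and `pre` (constant state on the pre-history).
#' @export
initial_state <- function(model, nS0, nE0, nI0 = 0) {
  stopifnot(inherits(model, "delaykin_model"))
  sp <- model$species
  state0 <- stats::setNames(numeric(length(sp)), sp)
  s_idx <- grep("^S[0-9]*$", sp)
  i_idx <- grep("^I[0-9]+$", sp)
  if (any(c(nS0, nE0, nI0) < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  state0[s_idx] <- rep_len(nS0, length(s_idx))
  if (length(i_idx)) state0[i_idx] <- rep_len(nI0, length(i_idx))
  e_name <- if ("E" %in% sp) "E" else if ("R00" %in% sp) "R00" else
    stop("model has no free-enzyme species", call. = FALSE)
  state0[e_name] <- nE0
  pre <- state0
  pre[s_idx] <- 0
  if (length(i_idx)) pre[i_idx] <- 0
  list(state0 = state0, pre = pre)
}

#' Evaluate the model right-hand side at one time point
#'
#' Reference (non-vectorized) evaluation of the compiled model's derivative
#' at time `t` given a history function. Distributed-delay terms are
#' discretized with [kernel_weights()] at resolution `step`. This is the
#' readable counterpart of the integrator's inner loop, intended for
#' inspection and testing; [integrate_model()] uses an equivalent compiled
#' path.
#'
#' @param model a compiled model.
#' @param t time (s).
#' @param history function mapping a time `<= t` to the (named or
#'   positional) state vector at that time.
#' @param step quadrature step (s) for distributed terms.
#' @param renormalize rescale quadrature weights to unit mass.
#' @return named derivative vector (conc/s).
#' @export
evaluate_rhs <- function(model, t, history, step = 0.05, renormalize = FALSE) {
  stopifnot(inherits(model, "delaykin_model"), is.function(history))
  n <- length(model$species)
  deriv <- stats::setNames(numeric(n), model$species)
  x_now <- unname(history(t))
  if (length(x_now) != n)
    stop("history must return a state vector of model dimension", call. = FALSE)
  for (ch in model$channels) {
    v <- switch(
      ch$delay$type,
      none = ch$rate * prod(x_now[ch$factors]),
      discrete = {
        hx <- unname(history(t - ch$delay$tau))
        ch$rate * prod(hx[ch$factors])
      },
      kernel = {
        w <- kernel_weights(ch$delay$kernel, ch$delay$rule, step,
                            renormalize = renormalize)
        vals <- vapply(w$lags, function(L) {
          prod(unname(history(t - L))[ch$factors])
        }, numeric(1))
        ch$rate * sum(w$weights * vals)
      }
    )
    deriv[ch$stoich$targets] <- deriv[ch$stoich$targets] + ch$stoich$coefs * v
  }
  deriv
}
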