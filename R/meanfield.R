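#' One step of the order-parameter mean-field map
#'
#' Thermodynamic-limit (`N -> Inf`, vanishing load) description of the
#' binary network with one condensed pattern. The state holds six numbers:
#' the firing fractions `m_plus`, `m_minus` and the synaptic variables
#' `x_plus`, `x_minus`, `u_plus`, `u_minus` averaged over the sublattices of
#' neurons active/quiescent in the pattern. Sublattice averaging of the
#' microscopic dynamics with the factorization `<x u s> ~ <x><u><s>` gives
#' the fields `h_plus = (1-a) * M`, `h_minus = -a * M` with
#' `M = x+ u+ m+ - x- u- m-`; the firing fractions follow the stochastic
#' update rule and the synaptic variables follow the discrete synapse map
#' with the firing indicator replaced by the sublattice firing fraction.
#'
#' @param v named numeric vector or list with `m_plus`, `m_minus`,
#'   `x_plus`, `x_minus`, `u_plus`, `u_minus`.
#' @param params a [tm_params()] object (MCS time constants).
#' @param T_noise temperature (>= 0).
#' @param a pattern activity.
#' @param theta scalar threshold.
#' @return named numeric vector: the mapped order parameters.
#' @export
mf_map_step <- function(v, params, T_noise, a = 0.5, theta = 0) {
  v <- unlist(v)[c("m_plus", "m_minus", "x_plus", "x_minus",
                   "u_plus", "u_minus")]
  M <- v["x_plus"] * v["u_plus"] * v["m_plus"] -
       v["x_minus"] * v["u_minus"] * v["m_minus"]
  h <- c((1 - a) * M, -a * M)
  d <- h - theta
  m_new <- if (T_noise == 0) {
    ifelse(d > 0, 1, ifelse(d < 0, 0, 0.5))
  } else {
    0.5 * (1 + tanh(2 * d / T_noise))
  }
  # synapse map with the *fraction* fired (mean-field s -> m)
  x <- c(v["x_plus"], v["x_minus"]); u <- c(v["u_plus"], v["u_minus"])
  m <- c(v["m_plus"], v["m_minus"])
  if (params$mode == "static") {
    x_new <- c(1, 1); u_new <- c(params$U, params$U)
  } else {
    if (params$mode == "depression") u <- c(1, 1)
    x_new <- x + (1 - x) / params$tau_rec - u * x * m
    if (params$mode == "depression") {
      u_new <- c(1, 1)
    } else if (params$tau_fac > 0) {
      u_new <- u + (params$U - u) / params$tau_fac + params$U * (1 - u) * m
    } else {
      u_new <- c(params$U, params$U)
    }
    x_new <- pmin(pmax(x_new, 0), 1)
    u_new <- pmin(pmax(u_new, 0), 1)
  }
  out <- c(m_new[1], m_new[2], x_new[1], x_new[2], u_new[1], u_new[2])
  names(out) <- c("m_plus", "m_minus", "x_plus", "x_minus",
                  "u_plus", "u_minus")
  out
}

mf_start_points <- function(params, a = 0.5) {
  U0 <- switch(params$mode, depression = 1, params$U)
  list(
    pattern = c(m_plus = 1, m_minus = 0, x_plus = 1, x_minus = 1,
                u_plus = U0, u_minus = U0),
    anti_pattern = c(m_plus = 0, m_minus = 1, x_plus = 1, x_minus = 1,
                     u_plus = U0, u_minus = U0),
    symmetric = c(m_plus = a, m_minus = a, x_plus = 1, x_minus = 1,
                  u_plus = U0, u_minus = U0))
}

#' Fixed points of the mean-field map
#'
#' Damped fixed-point iteration from deterministic starting points
#' (pattern, anti-pattern, symmetric), followed by deduplication. A point
#' `v` is accepted when `max|F(v) - v| < tol`.
#'
#' @inheritParams mf_map_step
#' @param tol convergence tolerance.
#' @param max_iter iteration cap per start.
#' @param damping mixing weight on the new iterate, in (0, 1].
#' @return list of named order-parameter vectors (possibly empty, with a
#'   warning if nothing converged).
#' @export
mf_find_fixed_points <- function(params, T_noise, a = 0.5, theta = 0,
                                 tol = 1e-10, max_iter = 5000,
                                 damping = 0.5) {
  stopifnot_scalar(tol, "tol", lower = 0, strict_lower = TRUE)
  found <- list()
  for (v0 in mf_start_points(params, a)) {
    v <- v0
    ok <- FALSE
    for (i in seq_len(max_iter)) {
      fv <- mf_map_step(v, params, T_noise, a, theta)
      if (max(abs(fv - v)) < tol) { ok <- TRUE; break }
      v <- (1 - damping) * v + damping * fv
    }
    if (ok) found <- c(found, list(v))
  }
  if (!length(found)) {
    warning("no fixed point converged from any start")
    return(list())
  }
  uniq <- list(found[[1]])
  for (v in found[-1]) {
    if (all(vapply(uniq, function(w) max(abs(w - v)) >= 10 * tol, TRUE)))
      uniq <- c(uniq, list(v))
  }
  uniq
}

#' Local stability of a mean-field fixed point
#'
#' Central-difference Jacobian of the map at `v` (step 1e-6); the point is
#' stable when all eigenvalue moduli are below 1.
#'
#' @inheritParams mf_map_step
#' @param fp_tol tolerance used to verify that `v` is a fixed point.
#' @return list with `is_stable`, `spectral_radius`, `jacobian`.
#' @export
mf_stability <- function(v, params, T_noise, a = 0.5, theta = 0,
                         fp_tol = 1e-6) {
  v <- unlist(v)
  fv <- mf_map_step(v, params, T_noise, a, theta)
  if (max(abs(fv - v)) > fp_tol)
    stop("'v' is not a fixed point within fp_tol", call. = FALSE)
  n <- length(v)
  J <- matrix(0, n, n)
  hstep <- 1e-6
  for (j in seq_len(n)) {
    vp <- v; vm <- v
    vp[j] <- vp[j] + hstep; vm[j] <- vm[j] - hstep
    J[, j] <- (mf_map_step(vp, params, T_noise, a, theta) -
               mf_map_step(vm, params, T_noise, a, theta)) / (2 * hstep)
  }
  sr <- max(Mod(eigen(J, only.values = TRUE)$values))
  list(is_stable = sr < 1, spectral_radius = sr, jacobian = J)
}

#' Classify the dynamical phase of the mean-field model
#'
#' `memory` when a stable fixed point with retrieval overlap
#' `|m_plus - m_minus| > 0.5` exists; otherwise `oscillatory` when the
#' long-run map iteration started near the pattern keeps a peak-to-peak
#' overlap amplitude above 0.1; otherwise `no-memory`.
#'
#' @inheritParams mf_map_step
#' @param transient,horizon iteration counts for the long-run amplitude
#'   probe.
#' @return character label.
#' @export
mf_classify_phase <- function(params, T_noise, a = 0.5, theta = 0,
                              transient = 2000, horizon = 2000) {
  fps <- withCallingHandlers(
    mf_find_fixed_points(params, T_noise, a, theta, tol = 1e-9),
    warning = function(w) invokeRestart("muffleWarning"))
  for (v in fps) {
    if (abs(v["m_plus"] - v["m_minus"]) > 0.5) {
      st <- mf_stability(v, params, T_noise, a, theta, fp_tol = 1e-5)
      if (st$is_stable) return("memory")
    }
  }
  # long-run amplitude: start slightly off the pattern
  v <- mf_start_points(params, a)$pattern
  v["m_plus"] <- 0.95; v["m_minus"] <- 0.05
  for (i in seq_len(transient)) v <- mf_map_step(v, params, T_noise, a, theta)
  ms <- numeric(horizon)
  for (i in seq_len(horizon)) {
    v <- mf_map_step(v, params, T_noise, a, theta)
    ms[i] <- v["m_plus"] - v["m_minus"]
  }
  if (diff(range(ms)) > 0.1) "oscillatory" else "no-memory"
}

#' Phase diagram over a two-parameter grid
#'
#' Evaluates [mf_classify_phase()] on a rectangular grid over any two of
#' `T_noise`, `tau_rec`, `tau_fac`, `U`.
#'
#' @param axes named list of two numeric vectors; names must be among
#'   `T_noise`, `tau_rec`, `tau_fac`, `U`.
#' @param params base [tm_params()] object supplying the fixed parameters.
#' @param T_noise base temperature (used unless `T_noise` is an axis).
#' @param a,theta network activity and threshold.
#' @return data frame with the two axis columns and a `phase` label column.
#' @export
mf_phase_diagram <- function(axes, params, T_noise = 0.1, a = 0.5,
                             theta = 0) {
  stopifnot(is.list(axes), length(axes) == 2,
            all(names(axes) %in% c("T_noise", "tau_rec", "tau_fac", "U")))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  grid$phase <- vapply(seq_len(nrow(grid)), function(i) {
    p <- params; Tn <- T_noise
    for (nm in names(axes)) {
      if (nm == "T_noise") Tn <- grid[[nm]][i] else p[[nm]] <- grid[[nm]][i]
    }
    p2 <- tm_params(U = p$U, tau_rec = p$tau_rec, tau_fac = p$tau_fac,
                    tau_in = p$tau_in, A = p$A, mode = p$mode)
    mf_classify_phase(p2, Tn, a, theta)
  }, character(1))
  grid
}
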