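#' Tsodyks-Markram dynamic-synapse parameters
#'
#' Container for the phenomenological short-term plasticity model. A synapse
#' holds a conserved pool of neurotransmitter resources split into recovered
#' (`x`), active (`y`) and inactive (`z`) fractions. Each presynaptic spike
#' releases a fraction `u * x` into the active state; active transmitter
#' inactivates with time constant `tau_in` and inactive transmitter recovers
#' with `tau_rec`. Facilitation makes the running release probability `u`
#' jump by `U * (1 - u)` at each spike and relax back with `tau_fac`.
#'
#' Time units are milliseconds for the continuous model and Monte Carlo
#' steps (MCS, roughly a 5 ms refractory period) for the discrete map used
#' in the binary network.
#'
#' @param U baseline release probability, in (0, 1].
#' @param tau_rec recovery time constant (ms or MCS), >= 0.
#' @param tau_fac facilitation time constant (ms or MCS), >= 0. `0` disables
#'   facilitation (`u` clamped at `U`).
#' @param tau_in inactivation time constant (ms); only used by the
#'   continuous model.
#' @param A maximal synaptic efficacy (pA); around 40 pA for cortical
#'   synapses.
#' @param mode `"dynamic"` for the full model, `"depression"` to clamp
#'   `u = 1` (pure depression, requires `U = 1`), `"static"` to clamp
#'   `x = 1, u = U` (no plasticity). Explicit flags avoid dividing by
#'   vanishing time constants when taking the static limit.
#' @return an object of class `tm_params`.
#' @export
tm_params <- function(U = 0.5, tau_rec = 100, tau_fac = 0, tau_in = 3,
                      A = 40, mode = c("dynamic", "depression", "static")) {
  mode <- match.arg(mode)
  stopifnot_scalar(U, "U", lower = 0, upper = 1, strict_lower = TRUE)
  stopifnot_scalar(tau_rec, "tau_rec", lower = 0)
  stopifnot_scalar(tau_fac, "tau_fac", lower = 0)
  stopifnot_scalar(tau_in, "tau_in", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(A, "A")
  if (mode == "depression" && U != 1)
    stop("depression-only mode clamps u = 1 and requires U = 1", call. = FALSE)
  structure(list(U = U, tau_rec = tau_rec, tau_fac = tau_fac,
                 tau_in = tau_in, A = A, mode = mode),
            class = "tm_params")
}

#' @export
print.tm_params <- function(x, ...) {
  cat(sprintf(
    "TM synapse [%s]: U=%g tau_rec=%g tau_fac=%g tau_in=%g A=%g pA\n",
    x$mode, x$U, x$tau_rec, x$tau_fac, x$tau_in, x$A))
  invisible(x)
}

#' Integrate the continuous dynamic-synapse model
#'
#' Event-driven integration of the three-state resource model plus the
#' facilitation variable. Between spikes all four variables relax linearly,
#' and the exact exponential solution is used (no delta-function
#' discretization error); at each spike time the jumps
#' `x -> x - u*x`, `y -> y + u*x`, `u -> u + U*(1-u)` are applied
#' atomically, with the release computed from the pre-spike `u`. Output is
#' sampled on a regular grid of step `dt`.
#'
#' @param params a [tm_params()] object.
#' @param spikes numeric vector of strictly increasing spike times (ms).
#' @param t_end end of the integration window (ms).
#' @param dt output sampling step (ms); must satisfy `dt < tau_in`.
#' @param state optional named list with initial `x`, `y`, `z`, `u`.
#' @return data frame with columns `t`, `x`, `y`, `z`, `u`.
#' @export
tm_integrate <- function(params, spikes = numeric(0), t_end, dt,
                         state = NULL) {
  stopifnot(inherits(params, "tm_params"))
  stopifnot_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(t_end, "t_end", lower = 0, strict_lower = TRUE)
  if (dt >= params$tau_in)
    stop("stability: dt must be smaller than tau_in", call. = FALSE)
  if (length(spikes) && any(diff(spikes) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (length(spikes) && any(spikes < 0))
    stop("spike times must be non-negative", call. = FALSE)
  st <- modifyList(list(x = 1, y = 0, z = 0, u = params$U), state %||% list())
  if (any(unlist(st[c("x", "y", "z")]) < -1e-12) ||
      abs(st$x + st$y + st$z - 1) > 1e-9)
    stop("initial state must satisfy x + y + z = 1 with fractions in [0,1]",
         call. = FALSE)

  grid <- seq(0, t_end, by = dt)
  out <- matrix(NA_real_, nrow = length(grid), ncol = 4L,
                dimnames = list(NULL, c("x", "y", "z", "u")))
  sp <- spikes[spikes <= t_end]
  x <- st$x; y <- st$y; z <- st$z; u <- st$u
  t_cur <- 0; isp <- 1L
  relax <- function(h) {
    # exact solution of the linear inter-spike dynamics
    if (h <= 0) return()
    ey <- exp(-h / params$tau_in)
    y_new <- y * ey
    if (params$tau_rec > 0) {
      er <- exp(-h / params$tau_rec)
      # z' = y/tau_in - z/tau_rec, with y(t) = y0 * exp(-t/tau_in)
      if (abs(params$tau_in - params$tau_rec) > 1e-12) {
        cf <- params$tau_rec / (params$tau_rec - params$tau_in)
        z_new <- z * er + y * cf * (er - ey)
      } else {
        z_new <- z * er + y * (h / params$tau_in) * ey
      }
    } else {
      z_new <- 0
    }
    x <<- 1 - y_new - z_new; y <<- y_new; z <<- z_new
    if (params$tau_fac > 0) {
      u <<- params$U + (u - params$U) * exp(-h / params$tau_fac)
    }
  }
  fire <- function() {
    rel <- if (params$mode == "depression") x else u * x
    if (params$mode != "static") {
      y <<- y + rel
      x <<- x - rel
    }
    if (params$mode == "dynamic" && params$tau_fac > 0) {
      u <<- u + params$U * (1 - u)
    }
  }
  for (i in seq_along(grid)) {
    tg <- grid[i]
    while (isp <= length(sp) && sp[isp] <= tg) {
      relax(sp[isp] - t_cur); t_cur <- sp[isp]
      fire()
      isp <- isp + 1L
    }
    relax(tg - t_cur); t_cur <- tg
    out[i, ] <- c(x, y, z, u)
  }
  data.frame(t = grid, out)
}

#' One step of the discrete dynamic-synapse map
#'
#' The per-step map used by the binary network, in MCS time units:
#' `x' = x + (1 - x)/tau_rec - u*x*s` and
#' `u' = u + (U - u)/tau_fac + U*(1 - u)*s`, with `s` the binary firing
#' indicator. In depression mode `u` is clamped to 1, in static mode
#' `x = 1, u = U`. Values are vectorized over synapses. Clipping to the
#' legal ranges is applied only as a floating-point guard (it is a no-op in
#' exact arithmetic) and reported via an attribute when triggered.
#'
#' @param x,u numeric vectors, current recovered fraction and release
#'   probability.
#' @param params a [tm_params()] object (time constants in MCS; must be
#'   >= 1 step in dynamic/depression mode).
#' @param fired binary vector (0/1) of presynaptic firing.
#' @return list with updated `x`, `u` and logical `clipped`.
#' @export
tm_step_discrete <- function(x, u, params, fired) {
  stopifnot(inherits(params, "tm_params"))
  if (!all(fired %in% c(0, 1))) stop("'fired' must be binary", call. = FALSE)
  if (params$mode == "static") {
    return(list(x = rep(1, length(x)), u = rep(params$U, length(x)),
                clipped = FALSE))
  }
  if (params$tau_rec < 1)
    stop("discrete map needs tau_rec >= 1 MCS (use mode = 'static')",
         call. = FALSE)
  if (params$mode == "depression") u <- rep(1, length(x))
  x_new <- x + (1 - x) / params$tau_rec - u * x * fired
  if (params$mode == "dynamic") {
    if (params$tau_fac > 0) {
      if (params$tau_fac < 1)
        stop("discrete map needs tau_fac >= 1 MCS (or tau_fac = 0)",
             call. = FALSE)
      u_new <- u + (params$U - u) / params$tau_fac +
        params$U * (1 - u) * fired
    } else {
      u_new <- rep(params$U, length(u))
    }
  } else {
    u_new <- u
  }
  clip_lo <- x_new < 0 | u_new < params$U - 1e-12
  clip_hi <- x_new > 1 | u_new > 1
  clipped <- any(clip_lo) || any(clip_hi)
  if (clipped) {
    x_new <- pmin(pmax(x_new, 0), 1)
    u_new <- pmin(pmax(u_new, params$U), 1)
  }
  list(x = x_new, u = u_new, clipped = clipped)
}

#' Steady-state synapse variables under Poisson firing
#'
#' Closed-form asymptotic release probability and recovered fraction for a
#' synapse driven at mean rate `f_n`:
#' `u_inf = U * (1 + tau_fac * f_n) / (1 + U * tau_fac * f_n)` and
#' `x_inf = 1 / (1 + u_inf * tau_rec * f_n)`. Rates are per unit of the
#' time constants (Hz when the constants are in seconds; use consistent
#' units).
#'
#' @param params a [tm_params()] object.
#' @param f_n presynaptic firing rate (>= 0), vectorized.
#' @return list with numeric vectors `u_inf` and `x_inf`.
#' @export
tm_steady_state <- function(params, f_n) {
  stopifnot(inherits(params, "tm_params"))
  if (any(f_n < 0)) stop("negative rate", call. = FALSE)
  if (params$mode == "static") {
    return(list(u_inf = rep(params$U, length(f_n)),
                x_inf = rep(1, length(f_n))))
  }
  U <- if (params$mode == "depression") 1 else params$U
  u_inf <- U * (1 + params$tau_fac * f_n) / (1 + U * params$tau_fac * f_n)
  if (params$mode == "depression") u_inf <- rep(1, length(f_n))
  x_inf <- 1 / (1 + u_inf * params$tau_rec * f_n)
  list(u_inf = u_inf, x_inf = x_inf)
}

#' Total postsynaptic current
#'
#' `I = sum_j A * y_j`, with `y_j` the active transmitter fraction of
#' synapse `j` and `A` the maximal efficacy in pA.
#'
#' @param A maximal synaptic efficacy (pA).
#' @param y numeric vector of active fractions in `[0, 1]`.
#' @return current in pA.
#' @export
postsynaptic_current <- function(A, y) {
  if (any(y < 0 | y > 1)) stop("y values must lie in [0, 1]", call. = FALSE)
  sum(A * y)
}
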