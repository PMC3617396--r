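#' Parameters of the bistable up-down rate model
#'
#' Stochastic mean-field model of a population of excitatory neurons with
#' noisy depressing synapses: the population rate `nu` relaxes toward a
#' sigmoidal function of the depressed recurrent input `J * nu * x - theta`
#' while the synaptic resource `x` recovers with `tau_r` and is consumed by
#' activity. Time is measured in units of the rate time constant `tau_nu`;
#' `tau_r` is a multiple of `tau_nu`.
#'
#' Units: `J` and `theta` are in volts and `nu` in `1/tau_nu` units with
#' maximum drive `nu_m`. The sigmoid width is stored in volts; note that
#' with `nu_m ~ 5e-3` the recurrent input spans only a few millivolts, so
#' the width must be sub-millivolt for the excitability to be genuinely
#' non-linear (see the package vignette).
#'
#' @param J synaptic strength (V).
#' @param theta activation threshold (V).
#' @param delta sigmoid width (V).
#' @param nu_m maximum drive (rate units).
#' @param tau_r synaptic recovery time (in `tau_nu` units).
#' @param U release parameter in `[0, 1]`.
#' @param D synaptic noise amplitude (the noise term in the resource
#'   equation has amplitude `D / tau_r`).
#' @param sigma_nu amplitude of the additive white noise on the rate
#'   equation (calibrated, not printed by the theory).
#' @param dt integration step (`tau_nu` units).
#' @return object of class `ud_params`.
#' @export
ud_params <- function(J = 1.2, theta = 1.2e-3, delta = 3e-4, nu_m = 5e-3,
                      tau_r = 1000, U = 0.6, D = 0, sigma_nu = 1e-3,
                      dt = 0.01) {
  stopifnot_scalar(tau_r, "tau_r", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(U, "U", lower = 0, upper = 1)
  stopifnot_scalar(D, "D", lower = 0)
  stopifnot_scalar(sigma_nu, "sigma_nu", lower = 0)
  stopifnot_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(delta, "delta", lower = 0, strict_lower = TRUE)
  structure(list(J = J, theta = theta, delta = delta, nu_m = nu_m,
                 tau_r = tau_r, U = U, D = D, sigma_nu = sigma_nu,
                 dt = dt),
            class = "ud_params")
}

#' Logistic excitability function
#'
#' `S(X) = 1 / (1 + exp(-X / delta))`.
#'
#' @param X input (V), vectorized.
#' @param delta width (V), > 0.
#' @return value in (0, 1).
#' @export
ud_sigmoid <- function(X, delta) {
  stopifnot_scalar(delta, "delta", lower = 0, strict_lower = TRUE)
  1 / (1 + exp(-X / delta))
}

#' Simulate the up-down rate model
#'
#' Euler-Maruyama integration (compiled core) of the coupled
#' rate/resource stochastic equations. `nu` is clipped to `[0, Inf)` and
#' `x` to `[0, 1]`; clip events are counted in the result.
#'
#' @param params a [ud_params()] object.
#' @param t_end simulated time (`tau_nu` units).
#' @param nu0,x0 initial conditions.
#' @param seed integer seed.
#' @param thin keep every `thin`-th sample in the output.
#' @return object of class `ud_trajectory`: data frame columns `t`, `nu`,
#'   `x`, with attributes `params` and `clipped`.
#' @export
ud_simulate <- function(params, t_end, nu0 = 0, x0 = 1, seed = 1L,
                        thin = 10L) {
  stopifnot(inherits(params, "ud_params"))
  if (params$dt > 0.01 * min(1, params$tau_r))
    stop("step size: need dt <= 0.01 * min(1, tau_r)", call. = FALSE)
  n_steps <- ceiling(t_end / params$dt)
  res <- with_seed(seed, ud_simulate_cpp(
    nu0, x0, as.integer(n_steps), params$dt, params$nu_m, params$J,
    params$theta, params$delta, params$tau_r, params$U, params$D,
    params$sigma_nu, as.integer(thin)))
  out <- data.frame(t = res$t, nu = res$nu, x = res$x)
  attr(out, "params") <- params
  attr(out, "clipped") <- res$clipped
  class(out) <- c("ud_trajectory", "data.frame")
  out
}

#' Effective potential of the rate dynamics at frozen resource level
#'
#' In the adiabatic picture (slow `x`) the rate obeys
#' `tau_nu dnu/dt = -Phi'(nu) + noise` with
#' `Phi(nu) = integral_0^nu (v - nu_m * S(J v x - theta)) dv`, evaluated
#' here in closed form via the softplus primitive of the logistic sigmoid.
#' Small `x` leaves a single low-activity minimum, large `x` a
#' high-activity one, intermediate `x` a bistable double well.
#'
#' @param x_fixed frozen resource level in `[0, 1]`.
#' @param params a [ud_params()] object.
#' @return a function `Phi(nu)`, vectorized over `nu`.
#' @export
ud_effective_potential <- function(x_fixed, params) {
  stopifnot(inherits(params, "ud_params"))
  stopifnot_scalar(x_fixed, "x_fixed", lower = 0, upper = 1)
  J <- params$J; th <- params$theta; dl <- params$delta; nm <- params$nu_m
  softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
  function(nu) {
    if (J * x_fixed == 0) {
      nu^2 / 2 - nm * ud_sigmoid(-th, dl) * nu
    } else {
      cfac <- dl / (J * x_fixed)
      nu^2 / 2 - nm * cfac *
        (softplus((J * nu * x_fixed - th) / dl) - softplus(-th / dl))
    }
  }
}

#' Detect up/down states and their permanence times
#'
#' Places a hysteresis band around the dip of the rate histogram: the two
#' dominant histogram modes are located, thresholds are set at
#' `dip +/- h` with `h` = 25% of the inter-mode distance, and the state
#' switches only on a full band crossing. Dwells shorter than
#' `min_samples` samples are merged into their neighbors.
#'
#' @param traj a [ud_simulate()] trajectory (or any data frame with `t`,
#'   `nu`).
#' @param n_bins histogram resolution.
#' @param min_samples minimum dwell length in samples (default 5).
#' @param min_side_mass each mode must carry at least this fraction of
#'   the total mass for the histogram to count as bimodal.
#' @return list with `up_durations`, `down_durations` (time units),
#'   `bimodal` flag, `thresholds`, `modes`. A unimodal histogram returns
#'   `bimodal = FALSE` and empty duration vectors (no-transition flag).
#' @export
ud_detect_states <- function(traj, n_bins = 80, min_samples = 5L,
                             min_side_mass = 0.02) {
  nu <- traj$nu
  if (length(nu) < 100) stop("trajectory too short", call. = FALSE)
  dt_s <- diff(traj$t[1:2])
  h <- graphics::hist(nu, breaks = n_bins, plot = FALSE)
  dens <- h$density; mids <- h$mids
  # smooth lightly, find local maxima
  k <- c(0.25, 0.5, 0.25)
  ds <- as.numeric(stats::filter(dens, k, sides = 2))
  ds[is.na(ds)] <- dens[is.na(ds)]
  loc_max <- which(diff(sign(diff(ds))) == -2) + 1L
  if (ds[1] > ds[2]) loc_max <- c(1L, loc_max)
  nb <- length(ds)
  if (ds[nb] > ds[nb - 1]) loc_max <- c(loc_max, nb)
  p1 <- p2 <- NA_integer_
  if (length(loc_max) >= 2) {
    ord <- loc_max[order(ds[loc_max], decreasing = TRUE)]
    p1 <- ord[1]
    # second mode: highest peak at least 3 bins away whose dip to the
    # main mode is genuinely deep
    for (cand in ord[-1][abs(ord[-1] - p1) >= 3L]) {
      dip_d <- min(ds[seq(min(p1, cand), max(p1, cand))])
      if (dip_d < 0.5 * ds[cand]) { p2 <- cand; break }
    }
  }
  ok <- !is.na(p2)
  if (ok) {
    dip_idx <- seq(min(p1, p2), max(p1, p2))
    dseg <- ds[dip_idx]
    # the whole inter-mode valley can sit at (near) zero density; center
    # the dip on the minimal-density plateau rather than its first bin
    at_min <- which(dseg <= min(dseg) + 1e-12 * max(ds))
    dip <- mids[dip_idx][at_min[ceiling(length(at_min) / 2)]]
    side_mass <- mean(nu > dip)
    if (min(side_mass, 1 - side_mass) < min_side_mass) ok <- FALSE
  }
  if (!ok) {
    return(list(up_durations = numeric(0), down_durations = numeric(0),
                bimodal = FALSE, thresholds = NULL,
                modes = mids[loc_max]))
  }
  lo_m <- min(mids[p1], mids[p2]); hi_m <- max(mids[p1], mids[p2])
  band <- 0.25 * (hi_m - lo_m)
  thr_lo <- dip - band; thr_hi <- dip + band
  # hysteresis state machine
  state <- if (nu[1] > dip) 1L else 0L
  states <- integer(length(nu))
  for (i in seq_along(nu)) {
    if (state == 0L && nu[i] > thr_hi) state <- 1L
    if (state == 1L && nu[i] < thr_lo) state <- 0L
    states[i] <- state
  }
  r <- rle(states)
  # merge dwells shorter than min_samples into the previous run
  if (length(r$lengths) > 1L) {
    i <- 2L
    while (i <= length(r$lengths)) {
      if (r$lengths[i] < min_samples) {
        r$lengths[i - 1L] <- r$lengths[i - 1L] + r$lengths[i]
        r$lengths <- r$lengths[-i]; r$values <- r$values[-i]
        if (i <= length(r$values) && r$values[i - 1L] == r$values[i]) {
          r$lengths[i - 1L] <- r$lengths[i - 1L] + r$lengths[i]
          r$lengths <- r$lengths[-i]; r$values <- r$values[-i]
        }
      } else i <- i + 1L
    }
  }
  n_runs <- length(r$lengths)
  interior <- if (n_runs > 2) 2:(n_runs - 1) else integer(0)
  up <- r$lengths[interior][r$values[interior] == 1L] * dt_s
  dn <- r$lengths[interior][r$values[interior] == 0L] * dt_s
  list(up_durations = up, down_durations = dn, bimodal = TRUE,
       thresholds = c(lo = thr_lo, hi = thr_hi),
       modes = c(lo_m, hi_m))
}

#' Maximum-likelihood comparison of exponential and power-law dwell models
#'
#' Continuous power law `p(x) ~ x^-alpha` for `x >= x_min` with `x_min`
#' chosen by Kolmogorov-Smirnov minimization, against a shifted
#' exponential fitted on the same tail; the models are compared by a
#' normalized (Vuong) log-likelihood-ratio test at significance 0.05. The
#' power law is selected only when it fits significantly better.
#'
#' @param durations numeric vector of dwell times (>= 200 required).
#' @param xmin_candidates optional candidate `x_min` values (defaults to
#'   up to 60 quantiles of the sample).
#' @return list with `model` (`"power_law"` or `"exponential"`),
#'   `alpha` (power-law exponent), `rate` (tail exponential rate),
#'   `x_min`, `loglik_ratio`, `p_value`, `n_tail`, `ks`.
#' @export
ud_fit_permanence <- function(durations, xmin_candidates = NULL) {
  x <- durations[is.finite(durations) & durations > 0]
  if (length(x) < 200)
    stop("need at least 200 dwell durations", call. = FALSE)
  xs <- sort(x)
  if (is.null(xmin_candidates)) {
    qs <- unique(stats::quantile(xs, probs = seq(0, 0.9, length.out = 60),
                                 names = FALSE, type = 1))
    xmin_candidates <- qs
  }
  best <- NULL
  for (xm in xmin_candidates) {
    tail_x <- xs[xs >= xm]
    n <- length(tail_x)
    if (n < 50) next
    alpha <- 1 + n / sum(log(tail_x / xm))
    # KS distance of the tail against the fitted power law
    emp <- seq_len(n) / n
    thr <- 1 - (tail_x / xm)^(1 - alpha)
    ks <- max(abs(emp - thr))
    if (is.null(best) || ks < best$ks)
      best <- list(x_min = xm, alpha = alpha, ks = ks, n_tail = n)
  }
  tail_x <- xs[xs >= best$x_min]
  rate <- 1 / mean(tail_x - best$x_min)
  lp <- log(best$alpha - 1) - log(best$x_min) -
    best$alpha * log(tail_x / best$x_min)
  le <- log(rate) - rate * (tail_x - best$x_min)
  d <- lp - le
  Rsum <- sum(d)
  sdd <- stats::sd(d)
  n <- length(d)
  p <- if (sdd == 0) 1 else
    2 * stats::pnorm(-abs(Rsum) / (sqrt(n) * sdd))
  model <- if (Rsum > 0 && p < 0.05) "power_law" else "exponential"
  list(model = model, alpha = best$alpha, rate = rate,
       x_min = best$x_min, loglik_ratio = Rsum, p_value = p,
       n_tail = n, ks = best$ks)
}

#' Classify the up-down dynamical phase
#'
#' Runs replicated simulations at the given parameters and labels the
#' regime: `P` (no transitions: unimodal rate histogram or too few
#' switches), `S` (resource-slaved: smoothed rate strongly correlated with
#' the resource and fast switching), `C` (power-law up-state permanence
#' times: the critical signature), else `E` (exponential permanence
#' times).
#'
#' @param params a [ud_params()] object.
#' @param t_end simulated time per replica (`tau_nu` units).
#' @param replicas number of replicated runs pooled for the dwell
#'   statistics.
#' @param seed integer seed.
#' @param min_events minimum pooled dwell count for a fit attempt.
#' @return list with `label` and the supporting statistics.
#' @export
ud_classify_phase <- function(params, t_end = 2e5, replicas = 2L,
                              seed = 1L, min_events = 200L) {
  ups <- numeric(0); downs <- numeric(0)
  slaved_votes <- 0; n_trans <- 0
  for (r in seq_len(replicas)) {
    traj <- ud_simulate(params, t_end, nu0 = 0, x0 = 1,
                        seed = child_seed(seed, r), thin = 10L)
    det <- ud_detect_states(traj)
    ups <- c(ups, det$up_durations); downs <- c(downs, det$down_durations)
    n_trans <- n_trans + length(det$up_durations)
    if (det$bimodal && length(det$up_durations) >= 3) {
      nu_s <- as.numeric(stats::filter(traj$nu, rep(1 / 51, 51), sides = 2))
      okk <- !is.na(nu_s)
      rate_switch <- length(det$up_durations) / t_end
      if (stats::cor(nu_s[okk], traj$x[okk]) > 0.9 &&
          rate_switch > 1 / (10 * params$tau_r))
        slaved_votes <- slaved_votes + 1
    }
  }
  if (n_trans < 3)
    return(list(label = "P", n_up = length(ups), fit = NULL))
  if (slaved_votes > replicas / 2)
    return(list(label = "S", n_up = length(ups), fit = NULL))
  if (length(ups) < min_events)
    return(list(label = "E", n_up = length(ups), fit = NULL,
                note = "too few events for a distribution fit"))
  fit <- ud_fit_permanence(ups)
  list(label = if (fit$model == "power_law") "C" else "E",
       n_up = length(ups), fit = fit)
}

#' Up-down phase map over a (D, tau_r) grid
#'
#' @param D_values,tau_r_values grid axes.
#' @param params base [ud_params()] (its `D`, `tau_r` are overridden).
#' @param ... passed to [ud_classify_phase()].
#' @return data frame with `D`, `tau_r`, `label`, `n_up`.
#' @export
ud_phase_grid <- function(D_values, tau_r_values, params = ud_params(),
                          ...) {
  grid <- expand.grid(D = D_values, tau_r = tau_r_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$D <- grid$D[i]; p$tau_r <- grid$tau_r[i]
    p$dt <- min(p$dt, 0.01 * min(1, p$tau_r))
    cl <- ud_classify_phase(p, ...)
    data.frame(D = grid$D[i], tau_r = grid$tau_r[i],
               label = cl$label, n_up = cl$n_up)
  })
  do.call(rbind, res)
}
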