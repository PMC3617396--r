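#' Homogeneous Poisson presynaptic spike trains
#'
#' @param N number of independent trains.
#' @param f_n rate in Hz (>= 0).
#' @param t_end duration in ms.
#' @param seed integer seed.
#' @return list of numeric vectors of spike times (ms).
#' @export
generate_poisson_trains <- function(N, f_n, t_end, seed = 1L) {
  if (f_n < 0) stop("negative rate", call. = FALSE)
  rate_ms <- f_n / 1000
  with_seed(seed, lapply(seq_len(N), function(i) {
    if (rate_ms == 0) return(numeric(0))
    n_exp <- max(10, ceiling(rate_ms * t_end + 6 * sqrt(rate_ms * t_end)))
    ts <- cumsum(rexp(n_exp, rate_ms))
    while (length(ts) && ts[length(ts)] < t_end) {
      ts <- c(ts, ts[length(ts)] + cumsum(rexp(n_exp, rate_ms)))
    }
    ts[ts <= t_end]
  }))
}

#' Steady-state statistics of the pooled synaptic current
#'
#' For `N` independent Poisson presynaptic neurons at rate `f_n` through
#' synapses at their asymptotic working point, the pooled current has
#' mean `I_bar = N * f_n * tau_in * I_p` and variance
#' `sigma2 = 0.5 * N * f_n * tau_in * I_p^2`, with single-event efficacy
#' `I_p = A * u_inf * x_inf`. The identity `sigma2 = 0.5 * I_bar * I_p`
#' holds by construction. Non-monotonicity of `sigma2` in `f_n` (for
#' depressing synapses) is what makes multiresonance possible.
#'
#' @param N presynaptic count.
#' @param f_n rate (Hz).
#' @param params [tm_params()] with ms time constants.
#' @return list with `I_p`, `mean`, `variance` (pA, pA^2).
#' @export
sr_current_stats <- function(N, f_n, params) {
  ss <- tm_steady_state(params, f_n / 1000)  # time constants in ms
  I_p <- params$A * ss$u_inf * ss$x_inf
  rate_ms <- f_n / 1000
  I_bar <- N * rate_ms * params$tau_in * I_p
  list(I_p = I_p, mean = I_bar,
       variance = 0.5 * N * rate_ms * params$tau_in * I_p^2)
}

#' Event-based Monte Carlo of the pooled shot-noise current
#'
#' Independent oracle for the closed-form current statistics: superpose
#' `N` Poisson trains whose every event injects an exponential pulse of
#' fixed amplitude `I_p = A * u_inf * x_inf` (the synapses at their
#' asymptotic working point, the stationary regime the closed form
#' describes) and measure the empirical mean and variance of the pooled
#' current. Note the full per-synapse simulation has a slightly larger
#' variance than the closed form because release amplitudes fluctuate
#' around the working point.
#'
#' @param N presynaptic count.
#' @param f_n rate (Hz).
#' @param params [tm_params()] (ms units).
#' @param t_end window (ms).
#' @param dt sampling step (ms).
#' @param seed integer seed.
#' @return list with `mean` and `variance` (pA, pA^2).
#' @export
sr_shotnoise_mc <- function(N, f_n, params, t_end = 20000, dt = 0.1,
                            seed = 1L) {
  ss <- tm_steady_state(params, f_n / 1000)
  I_p <- params$A * ss$u_inf * ss$x_inf
  n_steps <- round(t_end / dt)
  counts <- with_seed(seed,
                      stats::rbinom(n_steps, N, min(1, f_n / 1000 * dt)))
  decay <- exp(-dt / params$tau_in)
  y <- stats::filter(counts, decay, method = "recursive")
  I <- I_p * (as.numeric(y) - 0.5 * counts)
  I <- I[-(1:round(n_steps / 10))]  # drop transient
  list(mean = mean(I), variance = stats::var(I))
}

#' Configuration of the feed-forward resonance experiment
#'
#' A population of `N` Poisson presynaptic neurons drives, through
#' dynamic synapses, a leaky integrate-and-fire neuron whose firing
#' threshold adapts toward `theta0 + k * <I>` (a slow low-pass of the
#' input current). The adaptation keeps the mean distance to threshold
#' near `theta0` as the presynaptic rate varies, so firing is controlled
#' by the current *fluctuations* - the mechanism behind multiresonance. A
#' weak zero-mean sinusoidal signal is added to the input current; its
#' amplitude is expressed as a fraction of the rheobase gap (`theta0 / R`)
#' and must stay below 1 so the signal alone never fires the neuron.
#'
#' @param N presynaptic count.
#' @param synapse a [tm_params()] object (ms units).
#' @param f_s signal frequency (Hz).
#' @param signal_frac signal amplitude as a fraction of `theta0 / R`.
#' @param tau_m membrane time constant (ms).
#' @param R input resistance scale (mV per pA).
#' @param theta0 baseline threshold gap (mV).
#' @param k_adapt adaptation gain on the low-passed mean current.
#' @param tau_theta,tau_lp threshold and current low-pass time constants
#'   (ms); keep both well above `1000 / f_s` so adaptation does not track
#'   the signal itself.
#' @param refrac absolute refractory period (ms).
#' @param dt integration step (ms).
#' @param warmup discarded transient (ms).
#' @param periods number of whole signal periods scored.
#' @return object of class `sr_config`.
#' @export
sr_config <- function(N = 600, synapse = tm_params(U = 0.05, tau_rec = 800,
                                                   tau_fac = 2000,
                                                   tau_in = 3, A = 40),
                      f_s = 5, signal_frac = 0.5, tau_m = 10, R = 1,
                      theta0 = 4, k_adapt = 1, tau_theta = 2000,
                      tau_lp = 2000, refrac = 25, dt = 0.1,
                      warmup = 1000, periods = 20) {
  stopifnot(inherits(synapse, "tm_params"))
  if (signal_frac >= 1)
    stop("signal alone would reach threshold (signal_frac must be < 1)",
         call. = FALSE)
  if (min(tau_theta, tau_lp) < 2 * 1000 / f_s)
    warning("adaptation faster than ~2 signal periods will track ",
            "and cancel the signal")
  structure(list(N = as.integer(N), synapse = synapse, f_s = f_s,
                 signal_frac = signal_frac, tau_m = tau_m, R = R,
                 theta0 = theta0, k_adapt = k_adapt,
                 tau_theta = tau_theta, tau_lp = tau_lp, refrac = refrac,
                 dt = dt, warmup = warmup, periods = periods),
            class = "sr_config")
}

#' Canonical resonance experiment variants
#'
#' The calibrated stated world of the multiresonance experiment: 600
#' presynaptic neurons, threshold gap 4 (voltage units of `R` x pA), 25 ms
#' refractory period, 5 Hz signal at half the rheobase gap, and a 25-point
#' logarithmic rate grid over 0.15-1000 Hz. Variants: `"static"`
#' (non-plastic synapses, U = 0.1: single resonance peak), `"dynamic"`
#' (U = 0.05, tau_rec = 800 ms, tau_fac = 2000 ms: two peaks),
#' `"tau_rec_fast"` (tau_rec = 200 ms: the high-frequency peak moves up),
#' `"tau_fac_slow"` (tau_fac = 8000 ms: the low-frequency peak moves
#' down).
#'
#' @param variant experiment variant name.
#' @return list with `config` (an [sr_config()]) and `f_n_grid`.
#' @export
sr_experiment_config <- function(variant = c("dynamic", "static",
                                             "tau_rec_fast",
                                             "tau_fac_slow")) {
  variant <- match.arg(variant)
  syn <- switch(variant,
    static = tm_params(U = 0.1, A = 40, mode = "static"),
    dynamic = tm_params(U = 0.05, tau_rec = 800, tau_fac = 2000,
                        tau_in = 3, A = 40),
    tau_rec_fast = tm_params(U = 0.05, tau_rec = 200, tau_fac = 2000,
                             tau_in = 3, A = 40),
    tau_fac_slow = tm_params(U = 0.05, tau_rec = 800, tau_fac = 8000,
                             tau_in = 3, A = 40))
  list(config = sr_config(synapse = syn),
       f_n_grid = exp(seq(log(0.15), log(1000), length.out = 25)))
}

#' Simulate the postsynaptic neuron at one presynaptic rate
#'
#' @param config an [sr_config()].
#' @param f_n presynaptic Poisson rate (Hz).
#' @param seed integer seed.
#' @return list with `spikes` (times, ms), `rate` (binned rate trace, Hz),
#'   `rate_t` (bin centers), `signal_bin` (signal averaged per bin),
#'   `C0` helper inputs, and diagnostics (`I_mean`, `I_var`,
#'   `final_threshold`).
#' @export
sr_simulate_postsynaptic <- function(config, f_n, seed = 1L) {
  stopifnot(inherits(config, "sr_config"))
  dt <- config$dt
  period_ms <- 1000 / config$f_s
  t_total <- config$warmup + config$periods * period_ms
  n_steps <- round(t_total / dt)
  amp <- config$signal_frac * config$theta0 / config$R
  tt <- (seq_len(n_steps) - 1) * dt
  signal <- amp * sin(2 * pi * config$f_s * tt / 1000)
  syn <- config$synapse
  mode <- switch(syn$mode, static = 0L, dynamic = 1L, depression = 2L)
  # start synapses at their asymptotic working point and the adaptation
  # low-pass at the expected steady mean current (the stationary regime
  # the experiment assumes), so slow adaptation carries no start-up bias
  ss <- tm_steady_state(syn, f_n / 1000)
  lp0 <- sr_current_stats(config$N, f_n, syn)$mean
  res <- with_seed(seed, sr_simulate_cpp(
    config$N, f_n / 1000, dt, as.integer(n_steps),
    syn$U, syn$tau_rec, syn$tau_fac, syn$tau_in, syn$A, mode,
    signal, config$tau_m, config$R, 0, config$theta0, config$k_adapt,
    config$tau_theta, config$tau_lp, as.integer(round(config$refrac / dt)),
    lp0, ss$x_inf, ss$u_inf))
  spikes <- (res$spike_steps + 1) * dt
  keep <- tt >= config$warmup
  bin_w <- period_ms / 20
  edges <- seq(config$warmup, t_total, by = bin_w)
  ctrs <- edges[-length(edges)] + bin_w / 2
  sp <- spikes[spikes > config$warmup & spikes <= t_total]
  counts <- graphics::hist(sp, breaks = edges, plot = FALSE)$counts
  rate <- counts / (bin_w / 1000)  # Hz
  sig_bin <- amp * sin(2 * pi * config$f_s * ctrs / 1000)
  I_keep <- res$I_trace[keep]
  list(spikes = spikes, rate = rate, rate_t = ctrs, signal_bin = sig_bin,
       I_mean = mean(I_keep), I_var = stats::var(I_keep),
       final_threshold = res$final_threshold)
}

#' Power norm of signal detection
#'
#' Time-averaged product of the weak input signal and the output rate,
#' `C0 = <S(t) nu(t)>`, evaluated by the trapezoidal rule over an integer
#' number of signal periods on a common sampling grid.
#'
#' @param S signal samples.
#' @param nu rate samples (same grid).
#' @param dt grid spacing (any time unit).
#' @return scalar `C0`.
#' @export
power_norm <- function(S, nu, dt) {
  if (length(S) != length(nu)) stop("mismatched grids", call. = FALSE)
  n <- length(S)
  w <- rep(dt, n); w[1] <- w[n] <- dt / 2
  sum(w * S * nu) / ((n - 1) * dt)
}

#' Local maxima with prominence
#'
#' Minimal peak detector for short resonance curves: local maxima whose
#' topographic prominence exceeds `min_prom`.
#'
#' @param y numeric curve.
#' @param min_prom prominence threshold (same units as `y`).
#' @return data frame with `index`, `height`, `prominence`.
#' @export
find_peaks <- function(y, min_prom = 0) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(0), height = numeric(0),
                               prominence = numeric(0)))
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  # plateau-safe: require strictly greater than at least one neighbor side
  res <- lapply(idx, function(i) {
    # walk left until a higher point; track the minimum seen
    lmin <- y[i]; j <- i - 1L
    while (j >= 1 && y[j] <= y[i]) { lmin <- min(lmin, y[j]); j <- j - 1L }
    left_base <- if (j >= 1) lmin else min(y[1:i])
    rmin <- y[i]; j <- i + 1L
    while (j <= n && y[j] <= y[i]) { rmin <- min(rmin, y[j]); j <- j + 1L }
    right_base <- if (j <= n) rmin else min(y[i:n])
    prom <- y[i] - max(left_base, right_base)
    data.frame(index = i, height = y[i], prominence = prom)
  })
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0))
  out <- if (length(res)) do.call(rbind, res) else empty
  out[out$prominence > min_prom, , drop = FALSE]
}

#' Resonance curve of the power norm against the presynaptic rate
#'
#' Runs the feed-forward experiment over a grid of presynaptic rates with
#' replicated trials, and reports the mean power norm with its standard
#' error. Peaks are detected on the 3-point moving average with a
#' prominence threshold of 15% of the curve maximum.
#'
#' @param config an [sr_config()].
#' @param f_n_grid strictly increasing rate grid (Hz), >= 10 points.
#' @param trials trials per grid point (>= 5 recommended).
#' @param seed integer seed.
#' @return object of class `resonance_curve`: data frame with `f_n`, `C0`,
#'   `sem`; attribute `peaks` (data frame with `f_n`, `C0`, `prominence`).
#' @export
sr_resonance_curve <- function(config, f_n_grid, trials = 5, seed = 1L) {
  stopifnot(all(diff(f_n_grid) > 0))
  vals <- matrix(NA_real_, length(f_n_grid), trials)
  for (i in seq_along(f_n_grid)) {
    for (tr in seq_len(trials)) {
      sim <- sr_simulate_postsynaptic(config, f_n_grid[i],
                                      seed = child_seed(seed, i * 1000 + tr))
      vals[i, tr] <- power_norm(sim$signal_bin, sim$rate,
                                diff(sim$rate_t[1:2]))
    }
  }
  C0 <- rowMeans(vals)
  sem <- apply(vals, 1, stats::sd) / sqrt(trials)
  out <- data.frame(f_n = f_n_grid, C0 = C0, sem = sem)
  sm <- as.numeric(stats::filter(C0, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(C0[1:2]); sm[length(sm)] <- mean(C0[length(C0) - 1:0])
  pk <- find_peaks(sm, min_prom = 0.15 * max(sm))
  peaks <- data.frame(f_n = f_n_grid[pk$index], C0 = pk$height,
                      prominence = pk$prominence)
  attr(out, "peaks") <- peaks
  attr(out, "smoothed") <- sm
  class(out) <- c("resonance_curve", "data.frame")
  out
}

#' Peak-position control by the synapse time constants
#'
#' Computes resonance curves for several values of `tau_rec` (or
#' `tau_fac`) and tabulates the detected low- and high-frequency peak
#' positions. Increasing depression moves the high-frequency peak to lower
#' rates while the low-frequency peak stays put; increasing facilitation
#' moves the low-frequency peak.
#'
#' @param config base [sr_config()].
#' @param vary `"tau_rec"` or `"tau_fac"`.
#' @param values parameter values (>= 2).
#' @param f_n_grid,trials,seed passed to [sr_resonance_curve()].
#' @return data frame with `value`, `low_peak`, `high_peak`, `n_peaks`;
#'   curves attached as attribute `curves`. Curves without two peaks are
#'   flagged by `n_peaks != 2`.
#' @export
sr_peak_shift_analysis <- function(config, vary = c("tau_rec", "tau_fac"),
                                   values, f_n_grid, trials = 5,
                                   seed = 1L) {
  vary <- match.arg(vary)
  if (length(values) < 2) stop("need >= 2 parameter values", call. = FALSE)
  curves <- list()
  rows <- lapply(seq_along(values), function(i) {
    syn <- config$synapse
    syn[[vary]] <- values[i]
    syn2 <- tm_params(U = syn$U, tau_rec = syn$tau_rec,
                      tau_fac = syn$tau_fac, tau_in = syn$tau_in,
                      A = syn$A, mode = syn$mode)
    cfg <- config; cfg$synapse <- syn2
    cur <- sr_resonance_curve(cfg, f_n_grid, trials,
                              seed = child_seed(seed, i))
    curves[[i]] <<- cur
    pk <- attr(cur, "peaks")
    pk <- pk[order(pk$f_n), , drop = FALSE]
    data.frame(value = values[i],
               low_peak = if (nrow(pk)) pk$f_n[1] else NA_real_,
               high_peak = if (nrow(pk) >= 2) pk$f_n[nrow(pk)] else NA_real_,
               n_peaks = nrow(pk))
  })
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}
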