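#' Generate random binary activity patterns
#'
#' Draws `P` binary patterns of length `N` with mean activity `a`. In
#' balanced mode (default) every pattern has exactly `round(a * N)` active
#' neurons, so the overlap of a pattern with itself is exactly 1; in
#' unbalanced mode each entry is an independent Bernoulli(`a`) draw.
#'
#' @param N number of neurons (>= 2).
#' @param P number of patterns (>= 1).
#' @param a mean activity, in (0, 1).
#' @param balanced enforce exact per-pattern activity.
#' @param seed integer seed; the draw is reproducible.
#' @return object of class `pattern_set`: list with `xi` (P x N binary
#'   matrix), `a`, `balanced`.
#' @export
generate_patterns <- function(N, P, a = 0.5, balanced = TRUE, seed = 1L) {
  stopifnot_scalar(N, "N", lower = 2)
  stopifnot_scalar(P, "P", lower = 1)
  stopifnot_scalar(a, "a", lower = 0, upper = 1, strict_lower = TRUE)
  if (a >= 1) stop("'a' must be < 1", call. = FALSE)
  n_on <- round(a * N)
  if (balanced && n_on < 1)
    stop("balanced mode needs a*N >= 1", call. = FALSE)
  xi <- with_seed(seed, {
    if (balanced) {
      t(vapply(seq_len(P), function(mu) {
        v <- integer(N); v[sample.int(N, n_on)] <- 1L; v
      }, integer(N)))
    } else {
      matrix(as.integer(runif(N * P) < a), nrow = P)
    }
  })
  structure(list(xi = xi, a = a, balanced = balanced), class = "pattern_set")
}

#' Hebbian covariance weights
#'
#' Static synaptic conductances from the covariance learning rule:
#' `w_ij = 1/(N a (1-a)) * sum_mu (xi_i^mu - a)(xi_j^mu - a)`, with zero
#' self-connections. Symmetric by construction.
#'
#' @param patterns a [generate_patterns()] `pattern_set`.
#' @return N x N symmetric weight matrix with zero diagonal.
#' @export
hebbian_weights <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_set"))
  xi <- patterns$xi; a <- patterns$a
  N <- ncol(xi)
  ctr <- xi - a
  w <- crossprod(ctr) / (N * a * (1 - a))
  diag(w) <- 0
  w
}

#' Neuron firing thresholds
#'
#' `mode = "zero"` gives all-zero thresholds (the choice that makes the
#' depression-only network symmetric under pattern/anti-pattern exchange at
#' `a = 0.5`); `"half_row_sum"` gives `theta_i = 0.5 * sum_j w_ij`, the
#' value that maps the 0/1 network onto the classical +/-1 associative
#' memory in the static limit; `"custom"` passes `theta` through.
#'
#' @param w_bar weight matrix.
#' @param mode one of `"zero"`, `"half_row_sum"`, `"custom"`.
#' @param theta custom threshold vector (required for `"custom"`).
#' @return numeric N-vector of thresholds.
#' @export
thresholds <- function(w_bar, mode = c("zero", "half_row_sum", "custom"),
                       theta = NULL) {
  mode <- match.arg(mode)
  N <- nrow(w_bar)
  switch(mode,
    zero = rep(0, N),
    half_row_sum = 0.5 * rowSums(w_bar),
    custom = {
      if (is.null(theta) || length(theta) != N)
        stop("custom mode requires a length-N 'theta' vector", call. = FALSE)
      theta
    })
}

#' Local synaptic fields
#'
#' `h_i = sum_j w_ij * x_j * u_j * s_j`: the static weights modulated by the
#' per-neuron depression (`x`) and facilitation (`u`) variables of the
#' firing presynaptic neurons.
#'
#' @param w_bar N x N static weights.
#' @param s binary state vector.
#' @param x,u per-neuron synaptic variables.
#' @return numeric N-vector of fields.
#' @export
local_fields <- function(w_bar, s, x, u) {
  drop(w_bar %*% (x * u * s))
}

#' Stochastic parallel neuron update (Little dynamics)
#'
#' Every neuron is redrawn simultaneously from the fields of the current
#' state: `Prob(s_i = 1) = (1 + tanh(2 (h_i - theta_i) / T)) / 2`. At
#' `T = 0` this is the deterministic sign rule, with exact ties resolved by
#' a fair coin (the continuity limit of the update rule).
#'
#' @param h field vector.
#' @param theta threshold vector.
#' @param T_noise temperature (>= 0).
#' @return new binary state vector (uses the current RNG stream).
#' @export
update_neurons <- function(h, theta, T_noise) {
  stopifnot_scalar(T_noise, "T_noise", lower = 0)
  d <- h - theta
  if (T_noise == 0) {
    p <- ifelse(d > 0, 1, ifelse(d < 0, 0, 0.5))
  } else {
    p <- 0.5 * (1 + tanh(2 * d / T_noise))
  }
  as.integer(runif(length(h)) < p)
}

#' Overlap of a network state with a stored pattern
#'
#' `m = 1/(N a (1-a)) * sum_i (xi_i - a) * s_i`; equals 1 when the state
#' reproduces a balanced pattern and -1 on the anti-pattern at `a = 0.5`.
#'
#' @param s binary state vector.
#' @param xi binary pattern vector.
#' @param a pattern mean activity.
#' @return scalar overlap.
#' @export
overlap <- function(s, xi, a) {
  if (length(s) != length(xi)) stop("length mismatch", call. = FALSE)
  sum((xi - a) * s) / (length(s) * a * (1 - a))
}

#' Network configuration
#'
#' @param N neuron count.
#' @param T_noise temperature.
#' @param synapse a [tm_params()] object (time constants in MCS).
#' @param steps number of Monte Carlo steps.
#' @param seed integer seed.
#' @param theta_mode threshold mode, see [thresholds()].
#' @param theta custom threshold vector.
#' @return object of class `network_config`.
#' @export
network_config <- function(N, T_noise, synapse, steps, seed = 1L,
                           theta_mode = "zero", theta = NULL) {
  stopifnot_scalar(N, "N", lower = 2)
  stopifnot_scalar(T_noise, "T_noise", lower = 0)
  stopifnot_scalar(steps, "steps", lower = 1)
  stopifnot(inherits(synapse, "tm_params"))
  structure(list(N = as.integer(N), T_noise = T_noise, synapse = synapse,
                 steps = as.integer(steps), seed = as.integer(seed),
                 theta_mode = theta_mode, theta = theta),
            class = "network_config")
}

#' Monte Carlo simulation of the attractor network with dynamic synapses
#'
#' Synchronous stochastic dynamics of `N` binary neurons coupled through
#' Hebbian covariance weights modulated by one depression/facilitation
#' variable per neuron. The per-step order is fixed: fields are computed
#' from the current `(s, x, u)`, all neurons are redrawn, then the synaptic
#' variables are advanced using the pre-update firing state.
#'
#' @param config a [network_config()].
#' @param patterns a `pattern_set` (its `N` must match).
#' @param init either an integer pattern index (start exactly at that
#'   pattern), `"random"`, or a binary vector; `init_flip` optionally
#'   corrupts a pattern start by flipping that fraction of neurons.
#' @param init_flip fraction of neurons flipped in a pattern start.
#' @param record_raster keep the full spike raster (event list).
#' @return list with `trace` (data frame: `t`, per-pattern overlaps `m.*`,
#'   sublattice firing fractions `m_plus.*`, `m_minus.*` and synapse
#'   means `x_plus.*`, `x_minus.*`, `u_plus.*`, `u_minus.*`),
#'   `raster` (data frame `t`, `neuron` or NULL), and the final state.
#' @export
run_network <- function(config, patterns, init = 1L, init_flip = 0,
                        record_raster = FALSE) {
  stopifnot(inherits(config, "network_config"),
            inherits(patterns, "pattern_set"))
  N <- config$N
  if (ncol(patterns$xi) != N) stop("pattern length != N", call. = FALSE)
  P <- nrow(patterns$xi)
  a <- patterns$a
  w <- hebbian_weights(patterns)
  th <- thresholds(w, config$theta_mode, config$theta)
  syn <- config$synapse

  act <- lapply(seq_len(P), function(mu) which(patterns$xi[mu, ] == 1L))
  qui <- lapply(act, function(idx) setdiff(seq_len(N), idx))

  with_seed(config$seed, {
    s <- if (is.character(init) && identical(init, "random")) {
      as.integer(runif(N) < a)
    } else if (length(init) == 1L) {
      mu0 <- as.integer(init)
      if (mu0 < 1L || mu0 > P) stop("init pattern index out of range",
                                    call. = FALSE)
      s0 <- patterns$xi[mu0, ]
      if (init_flip > 0) {
        fl <- sample.int(N, round(init_flip * N))
        s0[fl] <- 1L - s0[fl]
      }
      s0
    } else {
      as.integer(init)
    }
    x <- rep(1, N)
    u <- rep(if (syn$mode == "depression") 1 else syn$U, N)

    steps <- config$steps
    m_tr <- matrix(NA_real_, steps + 1L, P)
    mp_tr <- mm_tr <- matrix(NA_real_, steps + 1L, P)
    xp_tr <- xm_tr <- up_tr <- um_tr <- matrix(NA_real_, steps + 1L, P)
    raster <- if (record_raster) vector("list", steps + 1L) else NULL
    snap <- function(t) {
      for (mu in seq_len(P)) {
        m_tr[t, mu] <<- overlap(s, patterns$xi[mu, ], a)
        mp_tr[t, mu] <<- mean(s[act[[mu]]]); mm_tr[t, mu] <<- mean(s[qui[[mu]]])
        xp_tr[t, mu] <<- mean(x[act[[mu]]]); xm_tr[t, mu] <<- mean(x[qui[[mu]]])
        up_tr[t, mu] <<- mean(u[act[[mu]]]); um_tr[t, mu] <<- mean(u[qui[[mu]]])
      }
      if (record_raster) raster[[t]] <<- which(s == 1L)
    }
    snap(1L)
    for (t in seq_len(steps)) {
      h <- local_fields(w, s, x, u)
      s_new <- update_neurons(h, th, config$T_noise)
      upd <- tm_step_discrete(x, u, syn, s)   # uses s(t), not s(t+1)
      x <- upd$x; u <- upd$u
      s <- s_new
      snap(t + 1L)
    }
    trace <- data.frame(t = 0:steps, m = m_tr, m_plus = mp_tr,
                        m_minus = mm_tr, x_plus = xp_tr,
                        x_minus = xm_tr, u_plus = up_tr, u_minus = um_tr)
    ras <- NULL
    if (record_raster) {
      ras <- data.frame(
        t = rep(0:steps, times = vapply(raster, length, 0L)),
        neuron = unlist(raster))
    }
    list(trace = trace, raster = ras,
         state = list(s = s, x = x, u = u))
  })
}

#' Dwell (permanence) times of an overlap trace
#'
#' Splits a single-pattern overlap trace into maximal runs with
#' `m > threshold` (pattern), `m < -threshold` (anti-pattern) or
#' transitional, merges runs shorter than `min_dwell` into their
#' neighbors, and returns the run lengths per attractor.
#'
#' @param m numeric overlap trace.
#' @param threshold detection threshold in (0, 1).
#' @param min_dwell minimum run length (steps) kept as a genuine visit.
#' @return list with integer vectors `pattern` and `anti_pattern` of dwell
#'   durations (in steps) and the full run table `runs`.
#' @export
permanence_times <- function(m, threshold = 0.5, min_dwell = 1L) {
  if (!length(m)) stop("empty trace", call. = FALSE)
  stopifnot_scalar(threshold, "threshold", lower = 0, upper = 1,
                   strict_lower = TRUE)
  lab <- ifelse(m > threshold, 1L, ifelse(m < -threshold, -1L, 0L))
  r <- rle(lab)
  # merge short runs into the previous surviving run
  keep_len <- r$lengths; keep_val <- r$values
  if (length(keep_len) > 1L) {
    i <- 2L
    while (i <= length(keep_len)) {
      if (keep_len[i] < min_dwell && length(keep_len) > 1L) {
        keep_len[i - 1L] <- keep_len[i - 1L] + keep_len[i]
        keep_len <- keep_len[-i]; keep_val <- keep_val[-i]
        # re-merge if neighbors now share a label
        if (i <= length(keep_val) && i > 1L &&
            keep_val[i - 1L] == keep_val[i]) {
          keep_len[i - 1L] <- keep_len[i - 1L] + keep_len[i]
          keep_len <- keep_len[-i]; keep_val <- keep_val[-i]
        }
      } else i <- i + 1L
    }
  }
  runs <- data.frame(label = keep_val, length = keep_len)
  list(pattern = runs$length[runs$label == 1L],
       anti_pattern = runs$length[runs$label == -1L],
       runs = runs)
}
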