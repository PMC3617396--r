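#' Reduced synapse parameters of the zero-temperature capacity theory
#'
#' At `T = 0` and activity 1/2 the steady-state effect of the dynamic
#' synapses on retrieval enters through two numbers: `gamma = U * tau_rec`
#' (effective depression) and
#' `gamma_prime = (1 + tau_fac) / (1 + U * tau_fac)` (effective
#' facilitation gain), plus the derived interference offset
#' `Delta = (1 + gamma * gamma_prime - gamma_prime) / gamma_prime`, which
#' vanishes in the static limit.
#'
#' @param U baseline release probability.
#' @param tau_rec,tau_fac synapse time constants (MCS).
#' @return list with `gamma`, `gamma_prime`, `Delta`.
#' @export
capacity_reduced_params <- function(U, tau_rec, tau_fac) {
  stopifnot_scalar(U, "U", lower = 0, upper = 1, strict_lower = TRUE)
  stopifnot_scalar(tau_rec, "tau_rec", lower = 0)
  stopifnot_scalar(tau_fac, "tau_fac", lower = 0)
  gamma <- U * tau_rec
  gamma_prime <- (1 + tau_fac) / (1 + U * tau_fac)
  list(gamma = gamma, gamma_prime = gamma_prime,
       Delta = (1 + gamma * gamma_prime - gamma_prime) / gamma_prime)
}

# Largest load alpha(y) admitting a retrieval solution at rescaled overlap y.
# Derived from the T=0 fixed-point system
#   M = erf(y),  y = M / sqrt(2 alpha (r + Delta^2)),  r = 1/(1 - C)^2,
#   C = (2/sqrt(pi)) y exp(-y^2) / erf(y),
# solved for alpha at given y.
capacity_alpha_of_y <- function(y, Delta) {
  C <- (2 / sqrt(pi)) * y * exp(-y^2) / erf(y)
  omc <- 1 - C
  ifelse(omc <= 0, 0,
         omc^2 * (erf(y) / y)^2 / (2 * (1 + omc^2 * Delta^2)))
}

#' Zero-temperature storage capacity with dynamic synapses
#'
#' Maximum load `alpha_c = P/N` at which the `T = 0` mean-field system for
#' the condensed-pattern overlap admits a solution with positive overlap.
#' The search bisects on `alpha` with a dense scan over the rescaled
#' overlap `y` at each load (a retrieval solution exists at load `alpha`
#' iff some `y > 0` supports it), down to the requested resolution. In the
#' static limit (`gamma -> 0`, `gamma_prime -> 1`) this reproduces the
#' classical 0.138 patterns-per-neuron bound, and no amount of depression
#' or facilitation can exceed that value.
#'
#' @param U baseline release probability.
#' @param tau_rec,tau_fac synapse time constants (MCS).
#' @param resolution bisection resolution on `alpha`.
#' @return scalar `alpha_c` (0 is a legal return).
#' @export
capacity_alpha_c <- function(U, tau_rec, tau_fac = 0, resolution = 1e-4) {
  rp <- capacity_reduced_params(U, tau_rec, tau_fac)
  ys <- exp(seq(log(0.02), log(8), length.out = 600))
  exists_solution <- function(alpha) {
    any(capacity_alpha_of_y(ys, rp$Delta) >= alpha)
  }
  lo <- 0; hi <- 0.2
  if (exists_solution(hi)) return(hi)  # cannot happen physically
  while (hi - lo > resolution / 4) {
    mid <- (lo + hi) / 2
    if (exists_solution(mid)) lo <- mid else hi <- mid
  }
  # polish: maximize alpha(y) near the best grid point
  av <- capacity_alpha_of_y(ys, rp$Delta)
  i <- which.max(av)
  o <- optimize(capacity_alpha_of_y,
                c(ys[max(1, i - 2)], ys[min(length(ys), i + 2)]),
                Delta = rp$Delta, maximum = TRUE, tol = 1e-12)
  max(lo, o$objective)
}

#' Capacity via direct iteration of the T = 0 mean-field system
#'
#' Independent route to the same quantity: for a given load the coupled
#' equations for the condensed overlap `M`, the rescaled overlap `y` and
#' the interference parameter `r` are solved by damped fixed-point
#' iteration started from perfect retrieval; `alpha_c` is the largest load
#' for which the iteration settles on `M > m_min`. Used as a cross-check of
#' [capacity_alpha_c()].
#'
#' @inheritParams capacity_alpha_c
#' @param m_min overlap below which a solution is considered lost.
#' @return scalar `alpha_c`.
#' @export
capacity_alpha_c_system <- function(U, tau_rec, tau_fac = 0,
                                    resolution = 1e-4, m_min = 0.1) {
  rp <- capacity_reduced_params(U, tau_rec, tau_fac)
  retrieves <- function(alpha) {
    if (alpha <= 0) return(TRUE)
    M <- 1; r <- 1
    for (i in 1:4000) {
      y <- M / sqrt(2 * alpha * (r + rp$Delta^2))
      M_new <- erf(y)
      C <- (2 / sqrt(pi)) * y * exp(-y^2) / max(M_new, 1e-300)
      r_new <- if (C < 1) 1 / (1 - C)^2 else Inf
      if (!is.finite(r_new)) return(FALSE)
      if (abs(M_new - M) < 1e-12 && abs(r_new - r) < 1e-9) {
        return(M_new > m_min)
      }
      M <- 0.5 * M + 0.5 * M_new
      r <- 0.5 * r + 0.5 * r_new
    }
    M > m_min
  }
  lo <- 0; hi <- 0.2
  while (hi - lo > resolution / 4) {
    mid <- (lo + hi) / 2
    if (retrieves(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
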