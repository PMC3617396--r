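test_that("sigmoid midpoint, saturation and monotonicity", {
  expect_equal(ud_sigmoid(0, 0.3), 0.5)
  expect_equal(ud_sigmoid(1e6, 0.3), 1)
  expect_equal(ud_sigmoid(-1e6, 0.3), 0)
  g <- ud_sigmoid(seq(-2, 2, by = 0.1), 0.4)
  expect_true(all(diff(g) > 0))
})

# deterministic fixed point of the noiseless system
noiseless_fp <- function(p) {
  res <- function(z) {
    nu <- z[1]; x <- z[2]
    c(-nu + p$nu_m * ud_sigmoid(p$J * nu * x - p$theta, p$delta),
      (1 - x) / p$tau_r - p$U * x * nu)
  }
  z <- c(0, 1)
  for (i in 1:20000) z <- z + c(0.2, 50) * res(z) * c(1, 1 / 50)
  list(z = z, resid = max(abs(res(z))))
}

test_that("noiseless integration settles on the deterministic fixed point", {
  p <- ud_params(D = 0, sigma_nu = 0)
  fp <- noiseless_fp(p)
  expect_lt(fp$resid, 1e-8)
  traj <- ud_simulate(p, 30000, nu0 = 0, x0 = 1, seed = 1)
  tailrows <- tail(as.data.frame(traj), 100)
  expect_equal(mean(tailrows$nu), fp$z[1], tolerance = 1e-6 + 1e-3 * fp$z[1])
  expect_equal(mean(tailrows$x), fp$z[2], tolerance = 1e-3)
  # started exactly at the fixed point: negligible drift
  traj2 <- ud_simulate(p, 100, nu0 = fp$z[1], x0 = fp$z[2], seed = 2,
                       thin = 1L)
  expect_lt(max(abs(traj2$x - fp$z[2])), 1e-5)
  expect_lt(max(abs(traj2$nu - fp$z[1])), 1e-6)
})

test_that("U = 0 resource dynamics reduces to an OU process around 1", {
  # OU mean-reversion level 1 with sd D/sqrt(2 tau_r); keep the noise
  # small so the x <= 1 clip acts as a reflection at the mean (the
  # stationary law is then approximately half-normal below 1)
  p <- ud_params(U = 0, D = 2, tau_r = 100, sigma_nu = 0)
  traj <- ud_simulate(p, 60000, nu0 = 0, x0 = 1, seed = 3, thin = 1L)
  x <- traj$x[-(1:500000)]
  sd_th <- p$D / sqrt(2 * p$tau_r)
  expect_equal(mean(x), 1 - sd_th * sqrt(2 / pi), tolerance = 0.03)
  expect_equal(sd(x), sd_th * sqrt(1 - 2 / pi), tolerance = 0.15)
  # correlation time of order tau_r (folding at the boundary shortens it
  # relative to the free OU exp(-lag/tau_r))
  acf_at <- function(lag) cor(x[-(1:lag)],
                              x[-((length(x) - lag + 1):length(x))])
  ac_q <- acf_at(round(p$tau_r / p$dt / 4))
  ac_f <- acf_at(round(p$tau_r / p$dt))
  expect_gt(ac_q, 0.25)
  expect_gt(ac_f, 0.02)
  expect_lt(ac_f, ac_q)
})

test_that("noise scaling is linear-response at monostable parameters", {
  p1 <- ud_params(U = 0.6, tau_r = 50, D = 0, sigma_nu = 2e-4,
                  theta = 4e-3)    # deep down state, monostable
  p2 <- ud_params(U = 0.6, tau_r = 50, D = 0, sigma_nu = 4e-4,
                  theta = 4e-3)
  v <- function(p, s) var(ud_simulate(p, 20000, seed = s, thin = 1L)$nu)
  r <- mean(sapply(1:3, function(s) v(p2, s) / v(p1, s)))
  expect_equal(r, 4, tolerance = 0.35)
})

test_that("effective potential is stationary exactly at the fixed points", {
  p <- ud_params()
  for (x_f in c(0.45, 0.7, 1)) {
    Phi <- ud_effective_potential(x_f, p)
    nus <- seq(0, 1.3 * p$nu_m, length.out = 4000)
    f <- function(nu) -nu + p$nu_m * ud_sigmoid(p$J * nu * x_f - p$theta,
                                                p$delta)
    v <- f(nus)
    h <- 1e-8
    for (i in which(diff(sign(v)) != 0)) {
      r <- uniroot(f, nus[c(i, i + 1)], tol = 1e-14)$root
      dPhi <- (Phi(r + h) - Phi(r - h)) / (2 * h)
      expect_lt(abs(dPhi), 1e-7)
    }
  }
})

test_that("potential shape: down well at small x, up well at large x,
           bistable between", {
  p <- ud_params(J = 1.1)
  nus <- seq(0, 1.2 * p$nu_m, length.out = 2000)
  n_minima <- function(x_f) {
    y <- ud_effective_potential(x_f, p)(nus)
    sum(diff(sign(diff(y))) == 2)
  }
  argmin <- function(x_f) {
    y <- ud_effective_potential(x_f, p)(nus)
    nus[which.min(y)]
  }
  expect_lt(argmin(0.2), 0.1 * p$nu_m)    # down state globally stable
  expect_gt(argmin(1), 0.6 * p$nu_m)      # up state globally stable
  bistable <- vapply(seq(0.3, 0.9, by = 0.05), n_minima, 0L)
  expect_true(any(bistable >= 2))
})

test_that("state detection recovers constructed dwell times", {
  set.seed(13)
  plateau <- rep(rep(c(0.005, 0.0001), each = 200), 10)
  traj <- data.frame(t = seq_along(plateau) * 0.1,
                     nu = plateau + rnorm(length(plateau), 0, 2e-4))
  det <- ud_detect_states(traj)
  expect_true(det$bimodal)
  expect_true(all(abs(det$up_durations - 20) <= 0.3))
  expect_true(all(abs(det$down_durations - 20) <= 0.3))
  # detector idempotence: reconstruct a clean square wave from the states
  sq <- rep(c(det$modes[2], det$modes[1]), each = 200)
  traj2 <- data.frame(t = seq_along(sq) * 0.1, nu = sq)
  det2 <- ud_detect_states(traj2)
  expect_true(all(abs(det2$up_durations - 20) <= 0.2))
  # monostable trace -> no-transitions flag
  set.seed(14)
  flat <- data.frame(t = (1:5000) * 0.1,
                     nu = 0.005 + rnorm(5000, 0, 1e-4))
  expect_false(ud_detect_states(flat)$bimodal)
})

test_that("telegraph dwell means are recovered within 5%", {
  set.seed(15)
  lam <- 1
  dwells <- rexp(10000, lam)
  # build the telegraph trace on a fine grid and push it through detection
  lv <- rep(rep(c(0.005, 0.0001), length.out = length(dwells)),
            times = pmax(1, round(dwells / 0.01)))
  traj <- data.frame(t = seq_along(lv) * 0.01, nu = lv)
  det <- ud_detect_states(traj, min_samples = 1L)
  got <- mean(c(det$up_durations, det$down_durations))
  # detection drops dwells < 1 sample; compare against the same censoring
  kept <- pmax(1, round(dwells / 0.01)) * 0.01
  expect_equal(got, mean(kept), tolerance = 0.05)
})

test_that("dwell-model selection separates exponential from Pareto", {
  set.seed(16)
  fe <- ud_fit_permanence(rexp(10000, rate = 1))
  expect_equal(fe$model, "exponential")
  expect_equal(fe$rate, 1, tolerance = 0.03)
  xpar <- (1 - runif(10000))^(-1 / 1.5)   # Pareto, alpha = 2.5, x_min = 1
  fp <- ud_fit_permanence(xpar)
  expect_equal(fp$model, "power_law")
  expect_lt(abs(fp$alpha - 2.5), 0.1)
  expect_error(ud_fit_permanence(rexp(50)), "at least 200")
})

test_that("default parameters switch between two rate modes", {
  traj <- ud_simulate(ud_params(), 5e4, seed = 21)
  det <- ud_detect_states(traj)
  expect_true(det$bimodal)
  expect_gt(length(det$up_durations), 50)
  # the two modes straddle the histogram dip by construction
  expect_lt(det$modes[1], det$thresholds["lo"])
  expect_gt(det$modes[2], det$thresholds["hi"])
})

test_that("static-synapse limit never yields the critical label", {
  p <- ud_params(U = 0.04, tau_r = 1, D = 0)
  cl <- ud_classify_phase(p, t_end = 2e4, replicas = 1L, seed = 5)
  expect_true(cl$label %in% c("P", "E"))
})
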