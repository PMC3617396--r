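test_that("pattern generation respects activity and balance", {
  ps <- generate_patterns(100, 10, 0.1, balanced = TRUE, seed = 3)
  expect_equal(dim(ps$xi), c(10L, 100L))
  expect_true(all(rowSums(ps$xi) == 10))
  # rounding edge: a = 1 - 1/N -> row sum N - 1
  ps2 <- generate_patterns(5, 1, 0.8, balanced = TRUE, seed = 1)
  expect_equal(sum(ps2$xi), 4)
  # unbalanced large-N mean within 3 binomial sigma
  ps3 <- generate_patterns(10000, 1, 0.5, balanced = FALSE, seed = 9)
  expect_lt(abs(mean(ps3$xi) - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(generate_patterns(10, 1, 0.05, balanced = TRUE), "a\\*N")
  # identical seeds are bit-identical
  expect_identical(generate_patterns(50, 3, 0.3, seed = 7)$xi,
                   generate_patterns(50, 3, 0.3, seed = 7)$xi)
})

test_that("covariance weights match the hand-computed 4-neuron example", {
  w <- hebbian_weights(hand_pattern())
  # prefactor 1/(N a (1-a)) = 1, so w_12 = (0.5)(0.5) = 0.25
  expect_equal(w[1, 2], 0.25)
  expect_equal(w[1, 3], -0.25)
  expect_equal(diag(w), rep(0, 4))
  expect_equal(w, t(w))
  # adding the anti-pattern doubles every weight (identical covariances)
  ps2 <- structure(list(xi = rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)),
                        a = 0.5, balanced = TRUE), class = "pattern_set")
  expect_equal(hebbian_weights(ps2), 2 * w)
})

test_that("thresholds follow the selected mode", {
  w <- hebbian_weights(hand_pattern())
  expect_equal(thresholds(w, "zero"), rep(0, 4))
  # theta_1 = 0.5 (0.25 - 0.25 - 0.25) = -0.125
  expect_equal(thresholds(w, "half_row_sum")[1], -0.125)
  expect_equal(thresholds(matrix(0, 3, 3), "half_row_sum"), rep(0, 3))
  expect_error(thresholds(w, "custom"), "theta")
  expect_equal(thresholds(w, "custom", theta = 1:4), 1:4)
})

test_that("local fields match the brute-force double loop", {
  w <- hebbian_weights(hand_pattern())
  xi <- hand_pattern()$xi[1, ]
  expect_equal(local_fields(w, rep(0L, 4), rep(1, 4), rep(1, 4)),
               rep(0, 4))
  # s = xi, x = u = 1: h_1 = w_12 = 0.25
  expect_equal(local_fields(w, xi, rep(1, 4), rep(1, 4))[1], 0.25)
  set.seed(5)
  N <- 60
  ps <- generate_patterns(N, 3, 0.4, seed = 2)
  w2 <- hebbian_weights(ps)
  s <- as.integer(runif(N) < 0.4); x <- runif(N); u <- runif(N)
  brute <- numeric(N)
  for (i in 1:N) for (j in 1:N) brute[i] <- brute[i] +
      w2[i, j] * x[j] * u[j] * s[j]
  expect_equal(local_fields(w2, s, x, u), brute)
})

test_that("neuron update rule matches the tanh probability", {
  # deterministic limits
  set.seed(1)
  expect_equal(update_neurons(c(1, -1), c(0, 0), 0), c(1L, 0L))
  # tie at T = 0 fires with probability ~ 1/2
  set.seed(2)
  ties <- replicate(2000, update_neurons(0.3, 0.3, 0))
  expect_lt(abs(mean(ties) - 0.5), 3 * sqrt(0.25 / 2000))
  # h - theta = 0.05, T = 0.1: empirical rate vs 0.5 (1 + tanh(1))
  set.seed(3)
  draws <- replicate(20, mean(update_neurons(rep(0.05, 5000), 0, 0.1)))
  p_theory <- 0.5 * (1 + tanh(1))
  expect_lt(abs(mean(draws) - p_theory),
            3 * sqrt(p_theory * (1 - p_theory) / 1e5))
})

test_that("overlap normalization, symmetry, and CLT magnitude", {
  xi <- c(1L, 1L, 0L, 0L)
  expect_equal(overlap(xi, xi, 0.5), 1)
  expect_equal(overlap(1L - xi, xi, 0.5), -1)
  # anti-pattern symmetry for arbitrary states at a = 0.5
  set.seed(8)
  ps <- generate_patterns(40, 1, 0.5, seed = 4)
  for (i in 1:5) {
    s <- as.integer(runif(40) < 0.5)
    expect_equal(overlap(s, 1L - ps$xi[1, ], 0.5),
                 -overlap(s, ps$xi[1, ], 0.5))
  }
  # random state nearly orthogonal to an independent pattern
  ps2 <- generate_patterns(10000, 1, 0.5, seed = 5)
  set.seed(6)
  s <- as.integer(runif(10000) < 0.5)
  expect_lt(abs(overlap(s, ps2$xi[1, ], 0.5)), 5 / sqrt(10000))
})

test_that("runs are seed-reproducible and static retrieval works", {
  ps <- generate_patterns(120, 1, 0.5, seed = 1)
  cfg <- network_config(120, 0.025, dep_synapse(26), steps = 50, seed = 9)
  r1 <- run_network(cfg, ps, init = 1, record_raster = TRUE)
  r2 <- run_network(cfg, ps, init = 1, record_raster = TRUE)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$raster, r2$raster)
  # Hopfield limit: 10% corrupted pattern retrieved within 50 MCS
  ps5 <- generate_patterns(500, 1, 0.5, seed = 2)
  cfg5 <- network_config(500, 0.01, static_synapse(1), steps = 50,
                         seed = 3)
  r5 <- run_network(cfg5, ps5, init = 1, init_flip = 0.1)
  expect_gt(tail(r5$trace$m, 1), 0.95)
  expect_error(run_network(cfg5, ps5, init = 4), "out of range")
})

test_that("depression-induced switching and its tau_rec dependence", {
  dwell_mean <- function(tau_rec, seed) {
    ps <- generate_patterns(120, 1, 0.5, seed = seed)
    cfg <- network_config(120, 0.025, dep_synapse(tau_rec), steps = 3000,
                          seed = seed + 40)
    r <- run_network(cfg, ps, init = 1)
    pt <- permanence_times(r$trace$m, threshold = 0.8)
    mean(c(pt$pattern, pt$anti_pattern))
  }
  d26 <- mean(vapply(1:3, function(s) dwell_mean(26, s), 0))
  d50 <- mean(vapply(1:3, function(s) dwell_mean(50, s), 0))
  # larger tau_rec -> faster fatigue -> shorter dwellings
  expect_lt(d50, d26)
})

test_that("permanence time extraction on constructed traces", {
  expect_equal(permanence_times(rep(1, 40), 0.5)$pattern, 40L)
  sq <- rep(rep(c(1, -1), each = 25), 4)
  pt <- permanence_times(sq, 0.5)
  expect_true(all(pt$pattern == 25L))
  expect_true(all(pt$anti_pattern == 25L))
  # short transitional blips are merged into neighbors
  m <- c(rep(1, 30), 0.2, rep(1, 30), rep(-1, 40))
  pt2 <- permanence_times(m, 0.5, min_dwell = 3)
  expect_equal(pt2$pattern, 61L)
  expect_equal(pt2$anti_pattern, 40L)
  expect_error(permanence_times(numeric(0)), "empty")
})
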