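test_that("NFDS multipliers evaluate the printed formula", {
  expect_equal(nfds_weights(0.5, 0.1), c(1.05, 1.05))
  expect_equal(nfds_weights(0.3, 0), c(1, 1))
  expect_equal(nfds_weights(0.9, 0.1), c(1.01, 1.09))
})

test_that("neutral competition drifts around the initial frequency", {
  dfe <- dfe_model("fixed", s_d = 0.01)
  set.seed(20)
  finals <- vapply(1:40, function(s) {
    cfg <- competition_config(2000, U1 = 0, U2 = 0, dfe = dfe,
                              init_freq1 = 0.5, generations = 100)
    tail(simulate_competition(cfg)$trajectory$p1, 1)
  }, numeric(1))
  # fixation probability of a neutral lineage = its initial frequency, so
  # the replicate mean stays near 0.5; sd of p1 after t gens ~ sqrt(t/(2N))
  se <- sqrt(stats::var(finals) / length(finals))
  expect_lt(abs(mean(finals) - 0.5), 3 * max(se, 0.02))
})

test_that("subpopulation sizes always sum to N and absorption is permanent", {
  set.seed(21)
  dfe <- dfe_model("fixed", s_d = 0.001)
  cfg <- competition_config(500, U1 = 0, U2 = 0, dfe = dfe,
                            init_freq1 = 0.05, generations = 400)
  tr <- simulate_competition(cfg)
  expect_true(all(tr$trajectory$N1 + tr$trajectory$N2 == 500))
  p1 <- tr$trajectory$p1
  hit0 <- which(p1 %in% c(0, 1))
  if (length(hit0) > 0)
    expect_true(all(p1[hit0[1]:length(p1)] == p1[hit0[1]]))
})

test_that("NFDS drives the frequency from 0.1 toward the 0.5 fixed point", {
  # deterministic oracle: iterate the expectation map
  pmap <- function(p, s) {
    m <- nfds_weights(p, s)
    m[1] * p / (m[1] * p + m[2] * (1 - p))
  }
  p <- 0.1
  for (t in 1:300) p <- pmap(p, 0.2)
  expect_equal(p, 0.5, tolerance = 1e-6)
  set.seed(22)
  dfe <- dfe_model("fixed", s_d = 0.001)
  cfg <- competition_config(1e5, U1 = 0, U2 = 0, dfe = dfe, s_freq = 0.2,
                            init_freq1 = 0.1, generations = 300)
  tr <- simulate_competition(cfg)
  expect_lt(abs(tail(tr$trajectory$p1, 1) - 0.5), 0.05)
})

test_that("NFDS equilibrium with a constant fitness deficit matches the analytic root", {
  s_freq <- 0.1; delta <- 0.01
  p_eq <- nfds_equilibrium(s_freq, delta)
  # independent root: solve (1 + s(1-p))(1-delta) = (1 + s p) numerically
  root <- stats::uniroot(function(p)
    (1 + s_freq * (1 - p)) * (1 - delta) - (1 + s_freq * p), c(0, 1))$root
  expect_equal(p_eq, root, tolerance = 1e-8)
  # stochastic iteration of the marker-level update at N = 1e5
  set.seed(23)
  N <- 1e5; p <- 0.5
  traj <- numeric(400)
  for (t in 1:400) {
    m <- nfds_weights(p, s_freq)
    W1 <- p * (1 - delta); W2 <- (1 - p)
    pp <- m[1] * W1 / (m[1] * W1 + m[2] * W2)
    p <- stats::rbinom(1, N, pp) / N
    traj[t] <- p
  }
  expect_lt(abs(mean(traj[201:400]) - p_eq), 0.02)
})

test_that("s_freq = 0 with equal rates reproduces single-population behaviour", {
  set.seed(24)
  dfe <- dfe_model("fixed", s_d = 0.001)
  cfg <- competition_config(2e4, U1 = 0.5, U2 = 0.5, dfe = dfe, s_freq = 0,
                            init_freq1 = 0.5, generations = 200)
  tr <- simulate_competition(cfg)
  last <- tail(tr$trajectory, 1)
  pooled_mut <- (last$N1 * last$mean_mutations1 + last$N2 * last$mean_mutations2) /
    (last$N1 + last$N2)
  set.seed(25)
  mono <- simulate_population(2e4, 0.5, dfe, 200)
  # marker is neutral: pooled accumulation matches the monoclonal run
  expect_lt(abs(pooled_mut - mono$mean_mutations) / mono$mean_mutations, 0.1)
})

test_that("time_to_loss and mean_frequency operate on the trajectory window", {
  fake <- structure(list(trajectory = data.frame(
    generation = 0:10, N1 = 50, N2 = 50,
    p1 = c(rep(0.5, 7), 0.4, 0.2, 0.005, 0))), class = "competition_trajectory")
  expect_equal(time_to_loss(fake, 0.01), 9)
  expect_true(is.na(time_to_loss(structure(list(trajectory = data.frame(
    generation = 0:5, p1 = rep(0.5, 6))), class = "competition_trajectory"))))
  expect_equal(mean_frequency(fake, 0, 6), 0.5)
  expect_equal(mean_frequency(fake, 8, 8), 0.2)
  expect_error(mean_frequency(fake, 5, 20), "window")
})
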