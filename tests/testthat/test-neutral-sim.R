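test_that("transition matrix matches the matrix-exponential oracle on a rate grid", {
  skip_if_not_installed("Matrix")
  for (c in c(0.05, 0.2, 0.7)) for (e in c(0.1, 0.3, 1.2)) for (dt in c(0.5, 1, 3)) {
    P <- transition_probs(c, e, dt)
    Q <- matrix(c(-c, c, e, -e), 2, byrow = TRUE)
    expect_lt(max(abs(P - as.matrix(Matrix::expm(Q * dt)))), 1e-10)
    expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
  }
  # dt = 0: no time elapsed
  expect_equal(unname(transition_probs(0.3, 0.4, 0)), diag(2))
  # c = e, large dt: both rows -> (0.5, 0.5)
  expect_equal(unname(transition_probs(0.25, 0.25, 1e3)),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_error(transition_probs(0, 0.1), "positive")
})

test_that("closed-form expected richness matches the simulated ensemble", {
  p <- neutral_params(c = 0.1, e = 0.1, S_P = 100, S_0 = 20, dt = 1,
                      n_steps = 11)
  # fixed point at equilibrium start
  p_eq <- neutral_params(0.1, 0.1, 100, 50, 1, 5)
  expect_equal(expected_richness(p_eq, c(0, 3, 100)), rep(50, 3))
  # t -> infinity limit
  expect_equal(expected_richness(p, 1e6), 50)
  # frozen closed-form value at t = 5 (50 + (20-50)*exp(-1))
  expect_equal(expected_richness(p, 5), 38.96362, tolerance = 1e-6)
  # ensemble mean tracks the ODE solution within 3 MC standard errors
  set.seed(99)
  n_rep <- 3000L
  rich <- matrix(0, n_rep, p$n_steps)
  for (r in seq_len(n_rep))
    rich[r, ] <- colSums(sim_occ(p$c, p$e, p$S_P, p$S_0, years = 1:11))
  mean_rich <- colMeans(rich)
  mc_se <- apply(rich, 2, sd) / sqrt(n_rep)
  theo <- expected_richness(p, 0:10)
  expect_true(all(abs(mean_rich - theo) <= pmax(3 * mc_se, 1e-9)))
  # monotone transient from below
  expect_true(all(diff(expected_richness(p, 0:10)) > 0))
  expect_true(all(diff(expected_richness(
    neutral_params(0.1, 0.1, 100, 90, 1, 5), 0:10)) < 0))
})

test_that("simulation honours the initial condition, seed and limits", {
  p <- neutral_params(0.2, 0.3, 60, 25, 1, 10, seed = 123)
  s1 <- simulate_series(p)
  s2 <- simulate_series(p)
  expect_identical(s1$occupancy, s2$occupancy)  # determinism
  expect_identical(sum(s1$occupancy[, 1L]), 25L)
  expect_error(neutral_params(0.2, 0.3, 10, 11, 1, 10), "S_0")
  # extreme extinction: everything absent right after the start
  set.seed(7)
  occ <- sim_occ(1e-8, 50, 30, 30, years = 1:5)
  expect_true(all(occ[, -1L] == 0L))
})

test_that("stationary occupancy and lag-1 autocorrelation match theory", {
  # stationary fraction -> c/(c+e) on a long chain
  set.seed(4)
  occ <- sim_occ(0.2, 0.3, 200, 80, years = 1:5000)
  expect_equal(mean(occ), 0.4, tolerance = 0.01)
  # empirical lag-1 correlation of a long stationary chain vs exp(-(c+e)dt)
  expect_equal(lag1_autocorrelation(0.25, 0.25), exp(-0.5))
  set.seed(5)
  x <- as.vector(sim_occ(0.25, 0.25, 1, 1, years = 1:1000000))
  emp <- cor(x[-length(x)], x[-1L])
  expect_equal(emp, exp(-0.5), tolerance = 0.01)
  expect_equal(lag1_autocorrelation(0.1, 0.1, dt = 0), 1)
  expect_lt(lag1_autocorrelation(50, 50, 1), 1e-10)
})

test_that("rates_from_autocorrelation inverts the autocorrelation map", {
  r <- rates_from_autocorrelation(exp(-0.5), ratio = 1)
  expect_equal(unname(r), c(0.25, 0.25))
  r2 <- rates_from_autocorrelation(0.5, ratio = 2)
  expect_equal(unname(r2[["c"]] / r2[["e"]]), 2)
  expect_equal(unname(sum(r2)), log(2))
  for (rho in c(0.1, 0.37, 0.9)) for (ratio in c(0.5, 1, 3)) {
    rr <- rates_from_autocorrelation(rho, ratio)
    expect_equal(lag1_autocorrelation(rr[["c"]], rr[["e"]]), rho,
                 tolerance = 1e-12)
  }
  expect_error(rates_from_autocorrelation(1.2), "rho")
})

test_that("empirical rate estimator counts transitions over the span", {
  # 2 colonizations over a 10-year span
  occ <- rbind(a = c(0, 1, 1, 1, 1, 1), b = c(1, 1, 0, 0, 1, 1))
  s <- community_series("x", c(2000, 2002, 2004, 2006, 2008, 2010), occ)
  r <- estimate_rates(s)
  expect_equal(r[["c_hat"]], 2 / 10)
  expect_equal(r[["e_hat"]], 1 / 10)
  expect_equal(estimate_rates(s, length_type = "n_years")[["c_hat"]], 2 / 6)
  expect_equal(estimate_rates(s, per_species = TRUE)[["c_hat"]], 2 / 20)
  # constant community
  s0 <- community_series("y", 2000:2004, matrix(1, 2, 5))
  expect_equal(unname(estimate_rates(s0)), c(0, 0))
  # long-run consistency: in stationarity the colonization and extinction
  # event flows balance (ratio -> 1 whatever c/e), and the per-species event
  # rate matches the stationary flow P(absent) * P(absent -> present)
  set.seed(11)
  occ <- sim_occ(0.2, 0.1, 50, 33, years = 1:10000)
  s_long <- community_series("z", 1:10000, occ)
  r_long <- estimate_rates(s_long, per_species = TRUE)
  expect_equal(r_long[["c_hat"]] / r_long[["e_hat"]], 1, tolerance = 0.05)
  flow <- (0.1 / 0.3) * (0.2 / 0.3) * (1 - exp(-0.3))
  expect_equal(r_long[["c_hat"]], flow, tolerance = 0.05)
})
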