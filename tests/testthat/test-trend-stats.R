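test_that("per-series log-richness trend reproduces closed forms", {
  # exponential growth: doubling over 10 years -> slope = log(2)/10 exactly
  years <- 2000:2010
  rich <- 16 * 2^((years - 2000) / 10)
  fit <- richness_trend(rich, years = years)
  expect_equal(fit$slope, log(2) / 10, tolerance = 1e-12)
  expect_lt(fit$se, 1e-12)
  # constant richness: zero slope, boundary p
  fit0 <- richness_trend(rep(5, 8), years = 2001:2008)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$p_value, 1)
  # zero-richness years dropped by default, kept under log1p
  fitz <- richness_trend(c(0, 2, 3, 4, 5), years = 1:5)
  expect_equal(fitz$n_years, 4L)
  fitz2 <- richness_trend(c(0, 2, 3, 4, 5), years = 1:5, zero_years = "log1p")
  expect_equal(fitz2$n_years, 5L)
  expect_error(richness_trend(c(3, 4), years = 1:2), "at least 3")
})

test_that("stationary neutral batches have mean per-series slope near zero", {
  spec <- dataset_spec(n_series = 400, preset = "custom", length_mean = 25,
                       length_sd = 5, rho = 0.5, seed = 303)
  coll <- generate_neutral_dataset(spec)
  slopes <- vapply(coll$series, function(s) richness_trend(s)$slope,
                   numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes)), 3 * mc_se)
})

test_that("mixed trend recovers a planted fixed slope and degenerates sanely", {
  # parameter recovery: fixed slope 0.02, by-series slope sd 0.01
  set.seed(17)
  rows <- lapply(1:60, function(i) {
    yrs <- 2000:2019
    b_i <- rnorm(1, 0.02, 0.01)
    a_i <- rnorm(1, 2, 0.3)
    data.frame(series_id = paste0("s", i), year = yrs,
               value = a_i + b_i * (yrs - mean(yrs)) + rnorm(20, 0, 0.05))
  })
  fit <- mixed_trend(do.call(rbind, rows))
  expect_lt(abs(fit$fixed_slope - 0.02), 2 * fit$fixed_se)
  expect_true(fit$marginal_R2 >= 0 && fit$marginal_R2 <= fit$conditional_R2)
  expect_lte(fit$conditional_R2, 1)
  # near-identical series with almost no noise: slope equals the common OLS
  # slope and the model explains essentially everything
  rows2 <- lapply(1:8, function(i) {
    yrs <- 2000:2014
    data.frame(series_id = paste0("d", i), year = yrs,
               value = 1 + 0.03 * (yrs - mean(yrs)) + rnorm(15, 0, 1e-4))
  })
  fit2 <- suppressWarnings(mixed_trend(do.call(rbind, rows2)))
  expect_equal(fit2$fixed_slope, 0.03, tolerance = 1e-3)
  expect_gt(fit2$conditional_R2, 0.99)
})

test_that("heteroscedastic length-effect fit recovers generating coefficients", {
  set.seed(23)
  n <- 3000
  L <- sample(10:60, n, replace = TRUE)
  a0 <- 0.01; a1 <- 0; b0 <- -1; b1 <- -0.04
  y <- rnorm(n, a0 + a1 * L, exp(b0 + b1 * L))
  fit <- length_effect(y, L)
  cf <- coef(fit); se <- fit$se
  expect_lt(abs(cf["a1"] - a1), 2 * se["a1"])
  expect_lt(abs(cf["b1"] - b1), 2 * se["b1"])
  expect_lt(abs(cf["b0"] - b0), 3 * se["b0"])
  # nesting: full likelihood at least the homoscedastic submodel's
  expect_gte(fit$logLik, fit$logLik_homosced - 1e-6)
  # fitted sd positive at every observed length
  expect_true(all(predict(fit, sort(unique(L)))$sigma > 0))
  # homoscedastic truth: b1 recovered as indistinguishable from zero
  y2 <- rnorm(n, 0.01, 0.1)
  fit2 <- length_effect(y2, L)
  expect_lt(abs(coef(fit2)["b1"]), 2 * fit2$se["b1"])
  # percentile curves are ordered
  pc <- predict(fit, c(10, 30, 50), quantiles = c(0.1, 0.5, 0.9))
  expect_true(all(pc$q0.1 < pc$q0.5 & pc$q0.5 < pc$q0.9))
  expect_error(length_effect(y[1:5], L[1:5]), "at least 10")
  expect_error(length_effect(y[1:20], rep(12, 20)), "distinct")
})

test_that("final-NICE t-test behaves at the null and guards degeneracy", {
  set.seed(5)
  v <- rnorm(200, 0, 0.3)
  tt <- nice_final_test(c(v, -v))  # exactly symmetric about 0
  expect_lt(abs(tt$t), 1e-10)
  expect_gt(tt$p_value, 0.999)
  expect_error(nice_final_test(rep(0.5, 10)), "degenerate")
  expect_error(nice_final_test(c(NA, NA, 0.2)), "at least 2")
})

test_that("NICE mixed trend recovers planted decay and flat trajectories", {
  set.seed(29)
  rows <- lapply(1:50, function(i) {
    yrs <- 2000:2019
    data.frame(series_id = paste0("n", i), year = yrs,
               value = rnorm(1, 0.4, 0.1) - 0.01 * (yrs - 2000) +
                 rnorm(20, 0, 0.05))
  })
  fit <- nice_trend(do.call(rbind, rows))
  expect_lt(abs(fit$fixed_slope - (-0.01)), 2 * fit$fixed_se)
  # all-constant trajectories: slope 0
  rows0 <- lapply(1:6, function(i)
    data.frame(series_id = paste0("c", i), year = 2000:2009,
               value = 0.2 + 0.001 * i))
  fit0 <- suppressWarnings(nice_trend(do.call(rbind, rows0)))
  expect_lt(abs(fit0$fixed_slope), 1e-8)
})

test_that("finite-window neutral series below equilibrium trend upward", {
  # the headline bias mechanism: start below equilibrium, strong
  # autocorrelation, short windows -> positive overall richness trend
  spec <- dataset_spec(n_series = 200, preset = "custom", length_mean = 15,
                       length_sd = 3, rho = 0.8, init = "fraction",
                       init_occupancy = 0.3, seed = 61)
  coll <- generate_neutral_dataset(spec)
  fit <- mixed_trend(coll)
  expect_gt(fit$fixed_slope, 0)
  expect_lt(fit$p_value, 0.01)
})
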