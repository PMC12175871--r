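test_that("population kappa of the copy model hits the closed-form endpoints", {
  pi5 <- rep(0.2, 5)
  expect_equal(expected_kappa(rater_model(1, pi5)), 1)
  expect_equal(expected_kappa(rater_model(0, pi5)), 0)
  expect_error(expected_kappa(rater_model(0.5, c(1, 0, 0, 0, 0))),
               "degenerate")
})

test_that("population kappa equals theta^2 and is monotone in theta", {
  set.seed(12)
  for (i in 1:10) {
    pi <- rgamma(5, 1) + 0.05
    pi <- pi / sum(pi)
    thetas <- seq(0, 1, by = 0.1)
    for (sch in c("identity", "linear", "quadratic")) {
      ks <- vapply(thetas, function(th)
        expected_kappa(rater_model(th, pi), sch), numeric(1))
      expect_equal(ks, thetas^2, tolerance = 1e-10)
      expect_true(all(diff(ks) > 0))
    }
  }
})

test_that("population kappa matches a large Monte-Carlo draw", {
  model <- rater_model(0.6, rep(0.2, 5))
  k_pop <- expected_kappa(model, "quadratic")
  M <- simulate_ratings(5e5, 2, model, seed = 77)
  est <- weighted_kappa(build_table(M[, 1], M[, 2], 1:5), "quadratic")
  expect_lt(abs(est$kappa - k_pop), 3 * est$se)
})

test_that("theta calibration round-trips through the population kappa", {
  expect_equal(calibrate_theta(1, rep(0.2, 5)), 1)
  expect_equal(calibrate_theta(0, rep(0.2, 5)), 0)
  set.seed(4)
  for (i in 1:5) {
    pi <- rgamma(5, 2) + 0.1
    pi <- pi / sum(pi)
    th <- calibrate_theta(0.61, pi)
    expect_lt(abs(expected_kappa(rater_model(th, pi)) - 0.61), 1e-6)
  }
  expect_error(calibrate_theta(1.2, rep(0.2, 5)), "0, 1")
})

test_that("simulated ratings honour the copy model mechanics", {
  pi <- pilot_marginal_synthetic()
  # theta = 1: every rater copies the truth
  M1 <- simulate_ratings(50, 6, rater_model(1, pi), seed = 5)
  expect_true(all(M1 == M1[, 1]))
  # concentrated marginal with theta = 0: every entry is that category
  M0 <- simulate_ratings(20, 3, rater_model(0, c(0, 0, 1, 0, 0) + 1e-12),
                         seed = 5)
  expect_true(all(M0 == 3L))
  # law of large numbers: cell frequencies match the marginal
  Mbig <- simulate_ratings(20000, 5, rater_model(0.6, pi), seed = 6)
  freq <- tabulate(Mbig, 5) / length(Mbig)
  mc_se <- sqrt(pi * (1 - pi) / length(Mbig))
  expect_true(all(abs(freq - pi) < 3 * mc_se + 1e-3))
  # identical seeds give bit-identical draws
  expect_identical(simulate_ratings(30, 4, rater_model(0.7, pi), seed = 9),
                   simulate_ratings(30, 4, rater_model(0.7, pi), seed = 9))
})

test_that("power is near 1 under extreme separation and reproducible", {
  cfg <- sim_config(n_videos = 60, n_raters = 6, kappa_true = 0.95,
                    kappa_null = 0.53, n_reps = 200, seed = 21,
                    marginal = rep(0.2, 5))
  pr <- estimate_power(cfg)
  expect_gt(pr$power, 0.99)
  expect_equal(pr$n_valid_reps, 200L)
  pr2 <- estimate_power(cfg)
  expect_identical(pr$power, pr2$power)
  expect_identical(pr$mean_kappa_hat, pr2$mean_kappa_hat)
})

test_that("the power result bookkeeping is internally consistent", {
  cfg <- sim_config(n_videos = 30, n_reps = 100, seed = 13)
  pr <- estimate_power(cfg)
  expect_equal(pr$power, pr$n_rejections / pr$n_valid_reps)
  expect_equal(pr$mc_se, sqrt(pr$power * (1 - pr$power) / pr$n_valid_reps))
})

test_that("minimum-n search returns the smallest grid point reaching the target", {
  cfg <- sim_config(n_raters = 6, kappa_true = 0.61, kappa_null = 0.53,
                    n_reps = 50, seed = 17)
  res0 <- find_min_n(0, grid = c(10L, 20L, 30L), cfg)
  expect_equal(res0$n_min, 10L)
  expect_true(all(diff(res0$power_curve$smoothed_power) >= 0))
  expect_error(find_min_n(0.8, grid = integer(0), cfg), "nonempty")
  # n_min is nonincreasing in kappa_true (coarse grid, fixed seeds)
  cfg_hi <- cfg; cfg_hi$kappa_true <- 0.85; cfg_hi$n_reps <- 150L
  cfg_lo <- cfg; cfg_lo$kappa_true <- 0.70; cfg_lo$n_reps <- 150L
  grid <- c(20L, 60L, 100L, 140L)
  n_hi <- find_min_n(0.8, grid, cfg_hi)$n_min
  n_lo <- find_min_n(0.8, grid, cfg_lo)$n_min
  if (is.na(n_lo)) n_lo <- Inf
  expect_lte(n_hi, n_lo)
})

test_that("degenerate-prone configurations abort with a diagnostic", {
  cfg <- sim_config(n_videos = 3, n_raters = 2, kappa_true = 0.9,
                    kappa_null = 0.5, n_reps = 200, seed = 3,
                    marginal = c(0.97, 0.01, 0.005, 0.005, 0.01))
  expect_error(estimate_power(cfg), "degenerate")
})
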