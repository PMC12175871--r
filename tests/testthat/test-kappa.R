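test_that("contingency tables cross-classify and drop NA pairs", {
  t1 <- build_table(c(1, 2), c(1, 2), categories = 1:2)
  expect_equal(diag(t1$counts), c(`1` = 1L, `2` = 1L), ignore_attr = TRUE)
  expect_equal(t1$n, 2L)
  t2 <- build_table(c(1, 1, 2, 2), c(1, 2, 1, 2), categories = 1:2)
  expect_true(all(t2$counts == 1L))
  t3 <- build_table(c(1, NA), c(1, 2), categories = 1:2)
  expect_equal(t3$n, 1L)
  expect_error(build_table(c(NA, NA), c(1, 2), 1:2), "zero subjects")
  expect_error(build_table(c(1, 3), c(1, 2), 1:2), "outside")
})

test_that("weighted kappa reproduces the hand-derived examples", {
  tab <- build_table(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 2, 2), 1:2)
  est <- weighted_kappa(tab, scheme = "identity")
  expect_equal(est$kappa, 2 / 3)
  expect_equal(est$po, 5 / 6)
  expect_equal(est$pe, 1 / 2)
  tab2 <- build_table(c(0, 1, 2, 0), c(0, 2, 2, 1), 0:2)
  est2 <- weighted_kappa(tab2, scheme = "quadratic")
  expect_equal(est2$po, 0.875)
  expect_equal(est2$pe, 0.59375)
  expect_equal(est2$kappa, 0.28125 / 0.40625, tolerance = 1e-12)
  # perfect agreement over >= 2 categories
  perfect <- build_table(c(1, 2, 3, 1), c(1, 2, 3, 1), 1:3)
  expect_equal(weighted_kappa(perfect)$kappa, 1)
  # degenerate marginals are an explicit error
  expect_error(weighted_kappa(matrix(c(5, 0, 0, 0), 2, 2)), "p_e = 1")
})

test_that("identity-weight kappa matches the pair-enumeration oracle and transposition is free", {
  set.seed(101)
  for (i in 1:60) {
    k <- sample(2:5, 1)
    counts <- random_table(k, sample(5:40, 1))
    core_ok <- tryCatch(weighted_kappa(counts, "identity"),
                        error = function(e) NULL)
    o <- oracle_unweighted_kappa(counts)
    if (is.null(core_ok)) {
      expect_true(is.na(o))
      next
    }
    expect_equal(core_ok$kappa, o, tolerance = 1e-12)
    # rater-swap symmetry for all three schemes
    for (sch in c("identity", "linear", "quadratic")) {
      a <- tryCatch(weighted_kappa(counts, sch)$kappa, error = function(e) NA)
      b <- tryCatch(weighted_kappa(t(counts), sch)$kappa, error = function(e) NA)
      expect_equal(a, b, tolerance = 1e-12)
    }
  }
})

test_that("kappa never exceeds observed agreement and is 1 iff all mass is diagonal", {
  set.seed(7)
  for (i in 1:40) {
    counts <- random_table(3, 30)
    est <- tryCatch(weighted_kappa(counts, "identity"), error = function(e) NULL)
    if (is.null(est)) next
    expect_lte(est$kappa, est$po + 1e-12)
    if (sum(diag(counts)) == sum(counts)) expect_equal(est$kappa, 1)
    else expect_lt(est$kappa, 1)
  }
})

test_that("large-sample SE scales as 1/sqrt(n) and vanishes for perfect agreement", {
  counts <- matrix(c(10, 3, 1, 2, 12, 2, 1, 3, 9), 3, 3)
  se1 <- weighted_kappa(counts, "quadratic")$se
  se4 <- weighted_kappa(counts * 4, "quadratic")$se
  expect_equal(se4, se1 / 2, tolerance = 1e-10)
  perfect <- diag(c(4, 5, 6))
  expect_equal(weighted_kappa(perfect)$se, 0, tolerance = 1e-12)
})

test_that("large-sample SE agrees with a nonparametric bootstrap on a small table", {
  counts <- matrix(c(12, 4, 1, 3, 15, 4, 2, 3, 10), 3, 3)
  est <- weighted_kappa(counts, "quadratic")
  # bootstrap oracle: resample subjects from the empirical pair distribution
  set.seed(2024)
  n <- sum(counts)
  idx <- rep(seq_len(9), as.vector(counts))
  boots <- replicate(10000, {
    cells <- tabulate(sample(idx, n, replace = TRUE), nbins = 9)
    k <- tryCatch(weighted_kappa(matrix(cells, 3, 3), "quadratic")$kappa,
                  error = function(e) NA_real_)
    k
  })
  expect_lt(abs(est$se - sd(boots, na.rm = TRUE)) / sd(boots, na.rm = TRUE),
            0.15)
})

test_that("normal-approximation CI and z-test match closed-form arithmetic", {
  expect_equal(kappa_ci(0.5, 0, 0.95), c(ci_low = 0.5, ci_high = 0.5))
  ci <- kappa_ci(0.5, 0.1, 0.95)
  expect_equal(unname(ci), c(0.5 - 1.959964 * 0.1, 0.5 + 1.959964 * 0.1),
               tolerance = 1e-6)
  ci90 <- kappa_ci(0, 1, 0.90)
  expect_equal(unname(ci90[2]), qnorm(0.95), tolerance = 1e-12)
  expect_error(kappa_ci(0.5, -0.1), ">= 0")

  tst <- kappa_z_test(0.61, 0.53, 0.04, alpha = 0.10)
  expect_equal(tst$z, 2.0)
  expect_equal(tst$p, 2 * pnorm(-2), tolerance = 1e-12)
  expect_true(tst$reject)
  null_case <- kappa_z_test(0.53, 0.53, 0, alpha = 0.10)
  expect_equal(null_case$z, 0)
  expect_equal(null_case$p, 1)
  expect_false(null_case$reject)
  expect_error(kappa_z_test(0.6, 0.5, 0), "> 0")
})

test_that("Landis-Koch bands and the sufficiency flag", {
  expect_equal(interpret_kappa(0.52), "moderate")
  expect_equal(interpret_kappa(0.63), "substantial")
  expect_equal(interpret_kappa(-0.05), "no agreement")
  expect_equal(interpret_kappa(c(0, 0.20, 0.21, 0.40, 0.41, 0.60, 0.61, 0.80,
                                 0.81, 1)),
               c("slight", "slight", "fair", "fair", "moderate", "moderate",
                 "substantial", "substantial", "almost perfect",
                 "almost perfect"))
  expect_true(is_sufficient_kappa(0.61))
  expect_false(is_sufficient_kappa(0.609))
  expect_error(interpret_kappa(1.2), "exceed 1")
})

test_that("cross-instrument kappa aligns supports by integer shift only", {
  # identical vectors after alignment give kappa 1
  est <- cross_instrument_kappa(c(0, 2, 4, 1, 3), c(1, 3, 5, 2, 4),
                                scale_a = 0:4, scale_b = 1:5)
  expect_equal(est$kappa, 1)
  # 4-band classification (1-4) vs expert (1-5): equals weighted kappa on the
  # 5-category union table built by hand
  a <- c(1, 2, 2, 3, 4, 4, 1, 3)
  b <- c(1, 3, 2, 3, 5, 4, 2, 2)
  est2 <- cross_instrument_kappa(a, b, scale_a = 1:4, scale_b = 1:5,
                                 scheme = "quadratic")
  byhand <- weighted_kappa(build_table(a - 1, b - 1, 0:4), "quadratic")
  expect_equal(est2$kappa, byhand$kappa, tolerance = 1e-12)
  expect_equal(est2$categories, 0:4)
  expect_error(cross_instrument_kappa(1, 1, scale_a = c(0, 2, 4),
                                      scale_b = 1:5),
               "consecutive")
})
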