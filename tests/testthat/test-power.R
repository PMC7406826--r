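test_that("Pearson machinery matches the covariance formula", {
  u <- c(1, 2, 3, 4, 5); v <- c(1, 3, 2, 5, 4)
  got <- pearson_test(u, v)
  expect_equal(got$estimate, brute_cor(u, v), tolerance = 1e-12)
  expect_equal(pearson_test(u, u)$estimate, 1)
  expect_equal(pearson_test(u, -v)$estimate, -got$estimate)
  expect_equal(pearson_test(u, v)$p.value,
               cor.test(u, v)$p.value, tolerance = 1e-12)
  expect_error(pearson_test(u, rep(1, 5)), "zero variance")
})

test_that("partial correlation is the residual correlation", {
  # reduction: no covariates equals plain Pearson
  set.seed(4)
  u <- rnorm(12); v <- rnorm(12)
  expect_equal(partial_correlation(u, v)$estimate, pearson_test(u, v)$estimate)

  # 8-row dataset against the brute-force residual oracle
  C <- cbind(c(1, 2, 1, 3, 2, 4, 3, 5), c(0, 1, 0, 1, 1, 0, 1, 0))
  u8 <- c(2.2, 3.1, 1.9, 4.4, 3.0, 5.2, 4.1, 6.3)
  v8 <- c(1.0, 2.5, 1.2, 3.8, 2.2, 4.9, 3.1, 5.5)
  D <- cbind(1, C)
  ru <- u8 - D %*% brute_ols(D, u8)
  rv <- v8 - D %*% brute_ols(D, v8)
  got <- partial_correlation(u8, v8, C)
  expect_equal(got$estimate, brute_cor(ru, rv), tolerance = 1e-10)
  expect_equal(got$df, 8 - 2 - 2)

  # outcome fully explained by covariates has ~zero partial correlation
  set.seed(9)
  C2 <- matrix(rnorm(60), 30, 2)
  v2 <- C2 %*% c(1, -2)
  u2 <- rnorm(30)
  expect_lt(abs(partial_correlation(u2, as.numeric(v2) + 1e-8 * rnorm(30), C2)$estimate), 0.05)
})

test_that("the pooled two-sample t matches hand computation", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  got <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$statistic, -3.674, tolerance = 1e-3)
  expect_equal(got$statistic, -two_sample_t(c(4, 5, 6), c(1, 2, 3))$statistic)
  expect_equal(got$p.value, t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Monte Carlo power behaves like a test of the indirect effect", {
  # null indirect effect: success rate near the type-I level
  null_p <- mc_power_indirect(n = 33, r_xm = 0, r_my = 0.65, r_xy = 0,
                              n_reps = 500, rng_seed = 2)
  expect_lte(null_p$power, 0.10)

  # power approaches 1 at large n
  big <- mc_power_indirect(n = 1000, n_reps = 200, rng_seed = 3)
  expect_gt(big$power, 0.99)

  # monotone in n within Monte Carlo error
  pc <- power_curve(c(20, 33, 60, 100), n_reps = 300, rng_seed = 5)
  for (i in 1:3)
    expect_gt(pc$power[i + 1] - pc$power[i], -2 * sqrt(pc$mc_se[i]^2 + pc$mc_se[i + 1]^2))

  # determinism and tidy output
  expect_identical(tidy(mc_power_indirect(n_reps = 50, rng_seed = 10)),
                   tidy(mc_power_indirect(n_reps = 50, rng_seed = 10)))
  expect_error(mc_power_indirect(r_xm = 0.9, r_my = 0.9, r_xy = -0.9),
               "positive definite")
})

test_that("the paths input convention builds the implied correlations", {
  # with a, b, c' as standardized paths the implied X-Y correlation is c' + ab
  S <- rsfcmed:::power_corr_matrix(0.5, 0.4, 0.2, input = "paths")
  expect_equal(S[1, 3], 0.2 + 0.5 * 0.4)
  expect_equal(S[2, 3], 0.4 + 0.5 * 0.2)
  expect_equal(S[1, 2], 0.5)
})
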