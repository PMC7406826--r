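test_that("path estimates match the brute-force normal equations", {
  # tiny hand-constructed dataset, no covariates
  x <- c(1, 2, 3, 4, 5, 6)
  m <- c(2.0, 2.5, 4.1, 3.9, 5.6, 5.9)
  y <- c(1.1, 2.3, 2.8, 4.5, 4.4, 6.2)
  f <- fit_paths(x, m, y)
  oa <- brute_ols(cbind(1, x), m)
  oy <- brute_ols(cbind(1, x, m), y)
  oc <- brute_ols(cbind(1, x), y)
  expect_equal(f$a, oa[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(f$b, oy[3], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(f$c_prime, oy[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(f$c, oc[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(f$ab, f$a * f$b)

  # outcome identical to the mediator forces b = 1, c' = 0
  f2 <- fit_paths(x, m, m)
  expect_equal(f2$b, 1, tolerance = 1e-10)
  expect_equal(f2$c_prime, 0, tolerance = 1e-10)
})

test_that("the OLS decomposition a*b + c' = c is exact with shared covariates", {
  set.seed(8)
  n <- 40
  x <- rnorm(n); C <- cbind(rnorm(n), rbinom(n, 1, 0.5), rnorm(n), rnorm(n))
  M <- matrix(rnorm(n * 50), n, 50)
  M[, 1:10] <- M[, 1:10] + outer(x, rep(0.5, 10))
  y <- 0.4 * M[, 1] + 0.3 * x + rnorm(n)
  for (v in c(1, 7, 25)) {
    f <- fit_paths(x, M[, v], y, C)
    expect_lt(abs(f$a * f$b + f$c_prime - f$c), 1e-8)
  }
  df <- data.frame(aaq = x, caps = y, age = C[, 1], sex = C[, 2],
                   bdi = C[, 3], des = C[, 4])
  vm <- voxelwise_mediation(mediation_input(df, M), B = 150, rng_seed = 4)
  expect_lt(max(abs(vm$a * vm$b + vm$c_prime - vm$c)), 1e-8)
})

test_that("bootstrap p-values are deterministic, floored, and in (0, 1]", {
  set.seed(12)
  n <- 30
  x <- rnorm(n); m <- 0.8 * x + rnorm(n); y <- 0.8 * m + rnorm(n)
  b1 <- bootstrap_paths(x, m, y, B = 400, rng_seed = 5)
  b2 <- bootstrap_paths(x, m, y, B = 400, rng_seed = 5)
  expect_identical(tidy(b1), tidy(b2))
  ps <- c(b1$p_a, b1$p_b, b1$p_ab, b1$p_c_prime)
  expect_true(all(ps >= 1 / 400 & ps <= 1))
  # a strong planted effect reaches the floor neighbourhood
  expect_lt(b1$p_a, 0.01)
  expect_error(bootstrap_paths(x, m, y, B = 50), "B")
})

test_that("voxel-wise runs are order-invariant and match single-voxel subsets", {
  set.seed(21)
  n <- 33
  x <- rnorm(n); C <- cbind(rnorm(n), rbinom(n, 1, 0.5), rnorm(n), rnorm(n))
  M <- matrix(rnorm(n * 8), n, 8)
  y <- rnorm(n)
  df <- data.frame(aaq = x, caps = y, age = C[, 1], sex = C[, 2],
                   bdi = C[, 3], des = C[, 4])
  full <- voxelwise_mediation(mediation_input(df, M), B = 200, rng_seed = 13)
  perm <- sample(8)
  shuffled <- voxelwise_mediation(mediation_input(df, M[, perm]), B = 200, rng_seed = 13)
  expect_equal(shuffled$p_ab, full$p_ab[perm])
  expect_equal(shuffled$ab, full$ab[perm])
  single <- voxelwise_mediation(mediation_input(df, M[, 3, drop = FALSE]),
                                B = 200, rng_seed = 13)
  expect_equal(single$p_ab, full$p_ab[3])

  # observed point maps are invariant to a joint relabelling of subjects
  ord <- sample(n)
  df2 <- df[ord, ]; M2 <- M[ord, ]
  relabeled <- voxelwise_mediation(mediation_input(df2, M2), B = 150, rng_seed = 2)
  expect_equal(relabeled$ab, full$ab, tolerance = 1e-10)
})

test_that("standardized fits equal manual z-scoring", {
  set.seed(30)
  n <- 25
  x <- 10 + 3 * rnorm(n); m <- 0.5 * x + rnorm(n); y <- m + rnorm(n)
  f1 <- fit_paths(x, m, y, standardize = TRUE)
  f2 <- fit_paths(as.numeric(scale(x)), as.numeric(scale(m)), as.numeric(scale(y)))
  expect_equal(f1$a, f2$a, tolerance = 1e-12)
  expect_equal(f1$b, f2$b, tolerance = 1e-12)
})

test_that("mediation inputs are validated", {
  df <- data.frame(id = 1:10, aaq = rnorm(10), caps = rnorm(10),
                   age = rnorm(10), sex = rbinom(10, 1, 0.5),
                   bdi = rnorm(10), des = rnorm(10))
  M <- matrix(rnorm(10 * 4), 10, 4)
  expect_s3_class(mediation_input(df, M), "mediation_input")
  expect_error(mediation_input(df[, -2], M), "aaq")
  expect_error(mediation_input(df, M[1:9, ]), "match")
  dfna <- df; dfna$caps[3] <- NA
  expect_error(mediation_input(dfna, M), "missing values")
  expect_error(mediation_input(df[1:7, ], M[1:7, ]), "subjects")
  # collinear design falls back to the pseudoinverse with a warning
  x <- rnorm(12); m <- rnorm(12); y <- rnorm(12)
  Cdup <- cbind(x, x)
  w <- capture_warnings(fit_paths(x, m, y, Cdup))
  expect_true(any(grepl("collinear", w)))
})
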