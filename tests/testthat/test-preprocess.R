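test_that("initial volumes are discarded from image and motion together", {
  m <- matrix(rnorm(200 * 6, sd = 0.01), 200, 6)
  v <- vol_from_matrix(matrix(rnorm(200 * 8), 200, 8), grid = c(2, 2, 2))
  out <- discard_initial(v, m, k = 4)
  expect_equal(dim(out$volume$data)[4], 196)
  expect_equal(nrow(out$motion), 196)
  expect_equal(out$volume$data[, , , 1], v$data[, , , 5])
  expect_equal(out$motion[1, ], m[5, ])

  ident <- discard_initial(v, m, k = 0)
  expect_identical(ident$volume$data, v$data)
  expect_error(discard_initial(v, m[1:100, ], k = 4), "match")
  v8 <- vol_from_matrix(matrix(rnorm(8 * 8), 8, 8), grid = c(2, 2, 2))
  expect_error(discard_initial(v8, matrix(0, 8, 6), k = 10), "discard")
})

test_that("framewise displacement follows the backward-difference formula", {
  expect_equal(compute_fd(matrix(1.2, 50, 6)), rep(0, 50))

  m <- matrix(0, 20, 6)
  m[10:20, 2] <- 0.3                     # translation step at t = 10
  fd <- compute_fd(m)
  expect_equal(fd[10], 0.3)
  expect_equal(fd[-10], rep(0, 19))

  m2 <- matrix(0, 20, 6)
  m2[5:20, 5] <- 0.01                    # rotation step: 50 mm * 0.01 rad
  fd2 <- compute_fd(m2)
  expect_equal(fd2[5], 0.5)
  expect_error(compute_fd(matrix(c(NA, rnorm(11)), 2, 6)), "finite")
})

test_that("motion exclusion fires on the stated criteria only", {
  qc0 <- motion_qc(matrix(0, 30, 6))
  expect_false(qc0$excluded)
  expect_length(qc0$reasons[[1]], 0)

  m <- matrix(0, 30, 6); m[15, 6] <- 0.03    # 0.03 rad is about 1.72 degrees
  qc1 <- motion_qc(m)
  expect_true(qc1$excluded)
  expect_equal(qc1$reasons[[1]], "rotation")

  m2 <- matrix(0, 30, 6); m2[seq(2, 30, 2), 1] <- 0.7  # alternating jumps
  fd2 <- compute_fd(m2)
  expect_gt(mean(fd2), 0.5)
  qc2 <- motion_qc(m2, fd2)
  expect_true(qc2$excluded)
  expect_true("mean_fd" %in% qc2$reasons[[1]])
})

test_that("raising exclusion thresholds never excludes more subjects", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rnorm(40 * 6, sd = 0.4), 40, 6)
    strict <- motion_qc(m, trans_thr = 1.0, rot_thr_deg = 1.0, fd_thr = 0.3)
    loose <- motion_qc(m, trans_thr = 1.5, rot_thr_deg = 1.5, fd_thr = 0.5)
    expect_true(strict$excluded >= loose$excluded)
  }
})

test_that("scrubbing flags one before and two after each bad volume", {
  expect_equal(ncol(scrubbing_regressors(rep(0.1, 20))), 0)

  fd <- rep(0.1, 20); fd[11] <- 0.7
  sp <- scrubbing_regressors(fd)
  expect_equal(colnames(sp), paste0("spike_", 10:13))
  expect_true(all(colSums(sp) == 1))
  expect_equal(which(sp[, 2] == 1), 11)

  fd2 <- rep(0.1, 20); fd2[2] <- 0.9      # clipping at the series start
  expect_equal(colnames(scrubbing_regressors(fd2)), paste0("spike_", 1:4))
})

test_that("Friston-24 columns hold the parameters, lags and squares", {
  expect_true(all(friston24(matrix(0, 10, 6)) == 0))

  m <- matrix(0, 10, 6)
  m[, 3] <- rep(c(0, 1), 5)               # 0/1 series: square equals itself
  f <- friston24(m)
  expect_equal(f[, "friston15"], f[, "friston03"])
  expect_equal(unname(f[1, "friston09"]), 0)   # lag zero-filled at t = 1
  expect_equal(unname(f[2:10, "friston09"]), m[1:9, 3])
  expect_equal(f[, "friston21"], f[, "friston09"]^2)
})

test_that("CompCor recovers a planted rank-1 confound and is flat on noise", {
  set.seed(99)
  T <- 100; nv <- 60
  s <- sin(2 * pi * (1:T) / 25)
  noise_ts <- outer(s, runif(nv, 0.5, 2)) + matrix(rnorm(T * nv, sd = 0.01), T, nv)
  m <- cbind(noise_ts, matrix(rnorm(T * 4), T, 4))
  v <- vol_from_matrix(m, grid = c(8, 8, 1))
  cc <- compcor(v, seq_len(nv), k = 3)
  # CompCor detrends by construction, so the recoverable part of the planted
  # signal is its detrended component
  s_dt <- residuals(lm(s ~ seq_len(T)))
  expect_gt(abs(cor(cc[, 1], s_dt)), 0.99)
  expect_equal(sum(cc[, 1]^2), 1)

  set.seed(1)
  vw <- vol_from_matrix(matrix(rnorm(196 * 500), 196, 500), grid = c(25, 20, 1))
  X <- rsfcmed:::vol_matrix(vw)
  sv <- svd(scale(X), nu = 0, nv = 0)
  expect_lt(sv$d[1] / sv$d[5], 3)

  expect_equal(dim(compcor(v, seq_len(nv), k = 0)), c(T, 0L))
  expect_warning(compcor(v, 1:2, k = 5), "components")
})

test_that("the nuisance design concatenates its blocks with unique labels", {
  T <- 60
  m <- cbind(matrix(rnorm(T * 3, sd = 0.01), T, 3),
             matrix(rnorm(T * 3, sd = 1e-4), T, 3))
  fd <- compute_fd(m)
  cc <- matrix(rnorm(T * 5), T, 5, dimnames = list(NULL, paste0("compcor", 1:5)))
  d <- build_nuisance(m, fd, cc)
  expect_equal(ncol(d), 24 + 0 + 5 + 1 + 1)
  expect_false(anyDuplicated(colnames(d)) > 0)

  fd2 <- fd; fd2[30] <- 0.9               # one spike -> 4 flagged volumes
  d2 <- build_nuisance(m, fd2, cc)
  expect_equal(ncol(d2), 35)
  expect_equal(colnames(d)[1:24], sprintf("friston%02d", 1:24))
  expect_equal(utils::tail(colnames(d2), 2), c("trend", "intercept"))
})

test_that("nuisance regression leaves residuals orthogonal to the design", {
  T <- 60
  m <- cbind(matrix(rnorm(T * 3, sd = 0.02), T, 3),
             matrix(rnorm(T * 3, sd = 1e-4), T, 3))
  d <- build_nuisance(m, compute_fd(m), matrix(rnorm(T * 3), T, 3,
                                               dimnames = list(NULL, paste0("compcor", 1:3))))
  # a voxel that is an exact linear combination of design columns vanishes
  combo <- unclass(d) %*% rnorm(ncol(d))
  v <- vol_from_matrix(cbind(combo, matrix(rnorm(T * 7), T, 7)), grid = c(2, 2, 2))
  res <- regress_out(v, d)
  expect_lt(max(abs(res$data[1, 1, 1, ])), 1e-8)

  Y <- rsfcmed:::vol_matrix(res)
  dn <- sweep(unclass(d), 2, sqrt(colSums(unclass(d)^2)), "/")
  expect_lt(max(abs(crossprod(dn, Y))), 1e-6)

  # intercept-only design mean-centres
  v2 <- vol_from_matrix(matrix(rnorm(T * 8), T, 8), grid = c(2, 2, 2))
  ic <- matrix(1, T, 1, dimnames = list(NULL, "intercept"))
  class(ic) <- c("nuisance_matrix", class(ic))
  res2 <- regress_out(v2, ic)
  expect_equal(rsfcmed:::vol_matrix(res2),
               scale(rsfcmed:::vol_matrix(v2), scale = FALSE),
               ignore_attr = TRUE)

  # rank-deficient design warns and still projects
  ddup <- cbind(unclass(ic), intercept2 = 1)
  class(ddup) <- c("nuisance_matrix", class(ddup))
  expect_warning(regress_out(v2, ddup), "rank deficient")
})
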