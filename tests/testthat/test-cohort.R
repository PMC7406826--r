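test_that("behavioural generation is reproducible and matches its marginals", {
  spec <- cohort_spec(n_subjects = 33, rng_seed = 7)
  b1 <- gen_behavior(spec)
  b2 <- gen_behavior(spec)
  expect_identical(b1, b2)

  big <- gen_behavior(cohort_spec(n_subjects = 2000, rng_seed = 11))
  expect_lt(abs(mean(big$aaq) - 39.89), 1)
  expect_lt(abs(sd(big$aaq) - 11.03), 1)
  expect_lt(abs(mean(big$caps) - 25.27), 1)
  expect_lt(abs(sd(big$caps) - 11.0), 1)
  expect_true(all(big$age >= 18 & big$age <= 65))
  expect_true(all(big$sex %in% 0:1))
})

test_that("cohort specification enforces its invariants", {
  expect_error(cohort_spec(n_subjects = 3), "identifiability")
  expect_error(cohort_spec(n_volumes = 4), "n_volumes")
  expect_error(cohort_spec(tr = 0), "tr")
  expect_error(cohort_spec(a_true = 1.2), "standardized")
  # overlapping regions rejected
  spec <- cohort_spec()
  expect_error(cohort_spec(seed_region = spec$seed_region,
                           target_region = spec$seed_region[1:10]),
               "disjoint")
  expect_error(cohort_spec(noise_region = prod(cohort_spec()$grid) + 5), "grid")
})

test_that("motion traces respect the spike model", {
  spec <- small_spec(spike_prob = 0)
  fd <- compute_fd(gen_motion(spec, 1))
  expect_lt(max(fd), 0.5)

  spec2 <- cohort_spec(n_subjects = 8, n_volumes = 10, grid = c(10, 10, 5),
                       spike_prob = 1, rng_seed = 3)
  fd2 <- compute_fd(gen_motion(spec2, 1))
  expect_gte(sum(fd2 > 0.5), 9)

  spec3 <- small_spec(spike_prob = 0, motion_jitter = 0)
  m <- gen_motion(spec3, 2)
  expect_true(all(m == 0))
  expect_true(all(compute_fd(m) == 0))

  # identical stream regardless of how the cohort is materialised
  expect_identical(gen_motion(spec, 3), gen_cohort(spec, "image")$motion[[3]])
})

test_that("planted nulls carry no predictor-mediator association", {
  spec <- cohort_spec(n_subjects = 200, a_true = 0, rng_seed = 19)
  ch <- gen_cohort(spec, "zmap")
  x_std <- (ch$behavior$aaq - 39.89) / 11.03
  r <- apply(ch$z[, spec$target_region], 2, function(z) cor(x_std, z))
  expect_lt(max(abs(r)), 0.15)
})

test_that("background voxels are independent of the predictor", {
  spec <- cohort_spec(n_subjects = 500, rng_seed = 23)
  ch <- gen_cohort(spec, "zmap")
  x_std <- (ch$behavior$aaq - 39.89) / 11.03
  bg <- setdiff(seq_len(prod(spec$grid)),
                c(spec$seed_region, spec$target_region, spec$noise_region))
  r <- apply(ch$z[, bg[seq(1, length(bg), by = 7)]], 2, function(z) cor(x_std, z))
  expect_lt(mean(abs(r)), 0.1)
})

test_that("planted paths are recovered and rise monotonically with a_true", {
  # recovery at large n on the fast path
  spec <- cohort_spec(n_subjects = 400, rng_seed = 29)
  ch <- gen_cohort(spec, "zmap")
  beh <- ch$behavior
  C <- cbind(beh$age, beh$sex, beh$bdi, beh$des)
  core <- region_core(spec$target_region, spec$grid)
  a_hat <- vapply(core, function(v)
    fit_paths(beh$aaq, ch$z[, v], beh$caps, C, standardize = TRUE)$a, numeric(1))
  expect_lt(abs(mean(a_hat) - spec$a_true), 0.1)

  # monotonicity of the mean recovered slope in a_true
  recovered <- vapply(c(0, 0.3, 0.65), function(a) {
    sp <- cohort_spec(n_subjects = 150, a_true = a, rng_seed = 41)
    co <- gen_cohort(sp, "zmap")
    xs <- (co$behavior$aaq - 39.89) / 11.03
    mean(apply(co$z[, sp$target_region], 2, function(z) cor(xs, z)))
  }, numeric(1))
  expect_true(all(diff(recovered) > 0))
})

test_that("cohort generation is deterministic and levels agree", {
  spec <- small_spec()
  c1 <- gen_cohort(spec, "zmap")
  c2 <- gen_cohort(spec, "zmap")
  expect_identical(c1$z, c2$z)
  expect_identical(c1$behavior, c2$behavior)
  # the image level shares the planted field with the fast path
  c3 <- gen_cohort(spec, "image")
  expect_identical(c1$zeta, c3$zeta)
  expect_length(c3$volumes, spec$n_subjects)
  expect_identical(dim(c3$volumes[[1]]$data), c(spec$grid, spec$n_volumes))
})

test_that("region core strips the boundary", {
  grid <- c(10, 10, 5)
  box <- rsfcmed:::region_from_box(grid, 3:7, 3:7, 2:4)
  core <- region_core(box, grid)
  expect_setequal(core, rsfcmed:::region_from_box(grid, 4:6, 4:6, 3))
})
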