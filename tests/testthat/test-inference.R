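test_that("the primary threshold is a strict inequality", {
  p <- c(1, 0.5, 0.0005, 0.001, 0.05)
  expect_equal(primary_threshold(p, 0.001), c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_false(any(primary_threshold(rep(1, 10), 0.001)))
  expect_error(primary_threshold(p, 0), "alpha")
})

test_that("connected components respect the chosen neighbourhood", {
  g <- c(4, 4, 4)
  face <- array(FALSE, g); face[2, 2, 2] <- TRUE; face[3, 2, 2] <- TRUE
  for (conn in c(6, 18, 26))
    expect_equal(nrow(connected_components(face, conn)$clusters), 1L)

  corner <- array(FALSE, g); corner[1, 1, 1] <- TRUE; corner[2, 2, 2] <- TRUE
  expect_equal(nrow(connected_components(corner, 26)$clusters), 1L)
  expect_equal(nrow(connected_components(corner, 18)$clusters), 2L)
  expect_equal(nrow(connected_components(corner, 6)$clusters), 2L)

  edge <- array(FALSE, g); edge[1, 1, 1] <- TRUE; edge[2, 2, 1] <- TRUE
  expect_equal(nrow(connected_components(edge, 18)$clusters), 1L)
  expect_equal(nrow(connected_components(edge, 6)$clusters), 2L)
})

test_that("component sizes agree with an exhaustive flood-fill oracle", {
  set.seed(14)
  for (conn in c(6, 18, 26)) {
    bin <- array(runif(5 * 5 * 3) < 0.4, c(5, 5, 3))
    got <- connected_components(bin, conn)
    oracle <- brute_components(bin, conn)
    expect_equal(sort(got$clusters$size),
                 sort(as.integer(table(oracle[oracle > 0]))))
    # label maps agree up to renaming
    for (l in seq_len(max(oracle))) {
      members <- which(oracle == l)
      expect_length(unique(got$label_map[members]), 1L)
    }
  }
})

test_that("cluster labels are ordered by size with deterministic ties", {
  bin <- array(FALSE, c(8, 4, 2))
  bin[1:3, 1, 1] <- TRUE        # size 3
  bin[6:7, 1, 1] <- TRUE        # size 2
  bin[6:7, 3, 1] <- TRUE        # size 2, later peak
  cl <- connected_components(bin, 6)$clusters
  expect_equal(cl$size, c(3L, 2L, 2L))
  expect_equal(cl$peak_x[2], 6L)
  expect_equal(cl$peak_y[2], 1L)
  expect_equal(cl$peak_y[3], 3L)
})

test_that("permutation FWE yields floored, monotone corrected p-values", {
  spec <- cohort_spec(n_subjects = 20, grid = c(8, 8, 4), rng_seed = 61)
  ch <- gen_cohort(spec, "zmap")
  inp <- mediation_input(ch$behavior, ch$z, grid = spec$grid,
                         mask = seq_len(prod(spec$grid)))
  f <- suppressWarnings(cluster_fwe(inp, B = 100, n_perm = 19,
                                    alpha_primary = 0.2, rng_seed = 3))
  tab <- tidy(f)
  if (nrow(tab)) {
    expect_true(all(tab$corrected_p >= 1 / 20))
    expect_true(all(tab$corrected_p <= 1))
    # corrected p nonincreasing in size
    expect_true(all(diff(tab$corrected_p[order(-tab$size)]) >= 0))
    expect_true(all(tab$sign %in% c(-1, 1)))
  }
  expect_length(f$null_max, 19)
  # observed maps match a standalone voxel-wise run at the same seed
  vm <- voxelwise_mediation(inp, B = 100, rng_seed = 3)
  expect_identical(f$maps$p_ab, vm$p_ab)
  expect_identical(f$maps$ab, vm$ab)
})

test_that("supra-threshold clusters are sign-homogeneous", {
  spec <- cohort_spec(n_subjects = 25, grid = c(8, 8, 4), rng_seed = 77)
  ch <- gen_cohort(spec, "zmap")
  inp <- mediation_input(ch$behavior, ch$z, grid = spec$grid,
                         mask = seq_len(prod(spec$grid)))
  f <- suppressWarnings(cluster_fwe(inp, B = 100, n_perm = 19,
                                    alpha_primary = 0.3, rng_seed = 9))
  tab <- tidy(f)
  ab_full <- array(NA_real_, spec$grid); ab_full[inp$mask] <- f$maps$ab
  for (l in tab$label) {
    signs <- sign(ab_full[f$label_map == l])
    expect_length(unique(signs), 1L)
  }
})
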