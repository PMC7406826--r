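#' Partition a seed mask into head, body and tail
#'
#' Splits a seed mask into three contiguous slabs of as-equal-as-possible
#' slice counts along the anterior-posterior axis; when the slice count is not
#' divisible by three the extra slices go to the head first, then the body.
#' This geometric thirds rule stands in for the manual, landmark-based
#' subregion boundaries used on real anatomy (which the package consumes as
#' pre-labelled masks in real-data mode).
#'
#' @param seed_mask Linear voxel indices (or logical array) of the seed.
#' @param grid Length-3 grid dimensions.
#' @param axis Anterior-posterior axis (1, 2 or 3; default 2). Lower slice
#'   indices are treated as anterior.
#' @return A `seed_set`: named list of linear-index vectors `head`, `body`,
#'   `tail`, whose union is the input and whose parts are disjoint.
#' @export
partition_seed <- function(seed_mask, grid, axis = 2) {
  idx <- mask_indices(seed_mask, grid)
  if (length(idx) == 0L) stopf("`seed_mask` is empty")
  if (!axis %in% 1:3) stopf("`axis` must be 1, 2 or 3")
  sl <- voxel_coords(idx, grid)[, axis]
  slices <- sort(unique(sl))
  S <- length(slices)
  if (S < 3L) stopf("seed spans only %d slice(s) along axis %d; need at least 3", S, axis)
  n3 <- S %/% 3L
  counts <- n3 + c((S %% 3L) >= 1L, (S %% 3L) >= 2L, 0L)
  part <- rep(1:3, counts)
  assign3 <- part[match(sl, slices)]
  out <- list(head = sort(idx[assign3 == 1L]),
              body = sort(idx[assign3 == 2L]),
              tail = sort(idx[assign3 == 3L]))
  structure(out, class = "seed_set", grid = grid, axis = axis)
}

#' Mean seed time series
#'
#' Unweighted mean across the seed voxels at every timepoint.
#'
#' @param v A [vol4d()] volume.
#' @param voxels Linear voxel indices (or logical array) of the seed.
#' @return Numeric vector of length T.
#' @export
seed_timeseries <- function(v, voxels) {
  idx <- mask_indices(voxels, grid_dim(v))
  if (length(idx) == 0L) stopf("seed voxel set is empty")
  rowMeans(vol_matrix(v)[, idx, drop = FALSE])
}

#' Seed-to-voxel correlation map
#'
#' Pearson correlation between a seed time series and every in-mask voxel time
#' series. Voxels with zero variance map to r = 0; their count is stored in
#' the `n_zero_variance` attribute.
#'
#' @param v A [vol4d()] volume.
#' @param seed_ts Seed time series of length T with nonzero variance.
#' @param brain_mask Linear indices or logical array; default all voxels.
#' @return 3D array of correlations (NA outside the mask), with attribute
#'   `n_zero_variance`.
#' @export
rsfc_map <- function(v, seed_ts, brain_mask = NULL) {
  T <- n_timepoints(v)
  if (length(seed_ts) != T) stopf("seed series length != T")
  check_finite(seed_ts, "seed_ts")
  if (sd(seed_ts) <= .Machine$double.eps) stopf("seed time series has zero variance")
  grid <- grid_dim(v)
  idx <- if (is.null(brain_mask)) seq_len(prod(grid)) else mask_indices(brain_mask, grid)
  Y <- vol_matrix(v)[, idx, drop = FALSE]
  s <- seed_ts - mean(seed_ts)
  Yc <- sweep(Y, 2, colMeans(Y))
  denom <- sqrt(colSums(Yc^2)) * sqrt(sum(s^2))
  zero <- denom <= .Machine$double.eps
  r <- as.vector(crossprod(Yc, s))
  r[!zero] <- r[!zero] / denom[!zero]
  r[zero] <- 0
  r <- pmin(1, pmax(-1, r))
  out <- array(NA_real_, grid)
  out[idx] <- r
  attr(out, "n_zero_variance") <- sum(zero)
  out
}

#' Fisher r-to-z transform
#'
#' Variance-stabilizing transform `z = atanh(r)`, with |r| clipped to
#' `1 - 1e-7` before the transform so the result stays finite.
#'
#' @param r Correlations in \[-1, 1\] (vector or array); NAs pass through.
#' @return Same shape as `r`, on the z scale.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stopf("|r| must not exceed 1")
  out <- atanh(pmin(1 - 1e-7, pmax(-1 + 1e-7, r)))
  attributes(out) <- attributes(r)
  out
}

#' Per-subject seed connectivity map
#'
#' Convenience wrapper: seed mean time series, seed-to-voxel Pearson map, and
#' Fisher z transform in one step.
#'
#' @inheritParams rsfc_map
#' @param seed_voxels Linear indices of the seed region.
#' @param subject_id,seed_label Metadata stored as attributes.
#' @return 3D Fisher-z array (class `conn_map`).
#' @export
seed_connectivity <- function(v, seed_voxels, brain_mask = NULL,
                              subject_id = NA_character_,
                              seed_label = NA_character_) {
  z <- fisher_z(rsfc_map(v, seed_timeseries(v, seed_voxels), brain_mask))
  structure(z, class = "conn_map", subject_id = subject_id,
            seed_label = seed_label, voxel_size = v$voxel_size)
}
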