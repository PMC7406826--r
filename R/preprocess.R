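#' Discard initial volumes
#'
#' Drops the first `k` volumes from a functional image and its motion trace,
#' the usual allowance for T1 equilibration at the start of a run.
#'
#' @param v A [vol4d()] volume.
#' @param motion T x 6 motion-parameter matrix (3 translations in mm, 3
#'   rotations in radians), aligned with `v`.
#' @param k Number of leading volumes to discard (default 4).
#' @return List with elements `volume` and `motion`, both shortened by `k`.
#' @export
discard_initial <- function(v, motion, k = 4) {
  if (!is_count(k)) stopf("`k` must be a count")
  T <- n_timepoints(v)
  motion <- as_motion(motion, T)
  if (T <= k) stopf("cannot discard %d volumes from a series of length %d", k, T)
  if (k == 0) return(list(volume = v, motion = motion))
  keep <- (k + 1):T
  list(volume = new_vol4d(v$data[, , , keep, drop = FALSE], v$voxel_size, v$tr),
       motion = motion[keep, , drop = FALSE])
}

as_motion <- function(m, T = NULL) {
  m <- as.matrix(m)
  if (ncol(m) != 6L) stopf("motion parameters must have 6 columns, got %d", ncol(m))
  check_finite(m, "motion")
  if (!is.null(T) && nrow(m) != T)
    stopf("motion rows (%d) do not match number of volumes (%d)", nrow(m), T)
  m
}

#' Framewise displacement
#'
#' Backward-difference framewise displacement: the sum of absolute volume-to-
#' volume changes of the three translations plus the three rotations converted
#' to arc length on a sphere of the given head radius.
#'
#' @param motion T x 6 matrix: translations in mm, rotations in radians.
#' @param head_radius Assumed head radius in mm (default 50).
#' @return Numeric vector of length T; the first element is 0.
#' @export
compute_fd <- function(motion, head_radius = 50) {
  motion <- as_motion(motion)
  if (nrow(motion) < 2L) stopf("framewise displacement needs at least 2 timepoints")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion quality control decision
#'
#' Applies the exclusion rule for excessive head motion: any translation above
#' `trans_thr` mm, any rotation above `rot_thr_deg` degrees, or mean framewise
#' displacement above `fd_thr` mm.
#'
#' @param motion T x 6 motion matrix (rotations in radians).
#' @param fd Framewise displacement series from [compute_fd()]; computed if
#'   missing.
#' @param trans_thr,rot_thr_deg,fd_thr Exclusion thresholds (1.5 mm, 1.5
#'   degrees, 0.5 mm).
#' @param subject_id Optional id copied into the report.
#' @return One-row tibble: `subject_id`, `max_abs_translation` (mm),
#'   `max_abs_rotation` (degrees), `mean_fd` (mm), `excluded`, and `reasons`
#'   (list-column of character vectors; empty iff not excluded).
#' @export
motion_qc <- function(motion, fd = NULL, trans_thr = 1.5, rot_thr_deg = 1.5,
                      fd_thr = 0.5, subject_id = NA_character_) {
  motion <- as_motion(motion)
  if (is.null(fd)) fd <- compute_fd(motion)
  if (length(fd) != nrow(motion)) stopf("`fd` length does not match motion rows")
  max_trans <- max(abs(motion[, 1:3]))
  max_rot_deg <- max(abs(motion[, 4:6])) * 180 / pi
  mfd <- mean(fd)
  reasons <- character(0)
  if (max_trans > trans_thr) reasons <- c(reasons, "translation")
  if (max_rot_deg > rot_thr_deg) reasons <- c(reasons, "rotation")
  if (mfd > fd_thr) reasons <- c(reasons, "mean_fd")
  tibble(subject_id = subject_id,
         max_abs_translation = max_trans,
         max_abs_rotation = max_rot_deg,
         mean_fd = mfd,
         excluded = length(reasons) > 0L,
         reasons = list(reasons))
}

#' Motion-scrubbing spike regressors
#'
#' One unit indicator column per volume flagged around high-motion timepoints:
#' for every `t` with `fd[t] > thr`, the volumes `t - n_before` through
#' `t + n_after` are flagged (clipped to the series), duplicates merged.
#'
#' @param fd Framewise displacement series.
#' @param thr FD threshold in mm (default 0.5).
#' @param n_before,n_after Volumes flagged before/after each bad timepoint
#'   (defaults 1 and 2).
#' @return T x K 0/1 matrix, one column per flagged volume, columns named
#'   `spike_<t>`; K = 0 when nothing is flagged.
#' @export
scrubbing_regressors <- function(fd, thr = 0.5, n_before = 1, n_after = 2) {
  check_finite(fd, "fd")
  T <- length(fd)
  bad <- which(fd > thr)
  flagged <- sort(unique(unlist(lapply(bad, function(t)
    max(1L, t - n_before):min(T, t + n_after)))))
  out <- matrix(0, T, length(flagged))
  if (length(flagged)) {
    out[cbind(flagged, seq_along(flagged))] <- 1
    colnames(out) <- paste0("spike_", flagged)
  }
  out
}

#' Friston 24-parameter motion regressor set
#'
#' The six rigid-body parameters, the same six lagged by one volume, and the
#' squares of both sets. Lagged rows at the first timepoint are zero-filled.
#'
#' @param motion T x 6 motion matrix.
#' @return T x 24 matrix, columns `friston01` .. `friston24`, ordered as
#'   current, lagged, current squared, lagged squared.
#' @export
friston24 <- function(motion) {
  motion <- as_motion(motion)
  if (nrow(motion) < 2L) stopf("Friston-24 needs at least 2 timepoints")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  colnames(out) <- sprintf("friston%02d", 1:24)
  out
}

#' CompCor noise components
#'
#' Principal-component time courses of the noise-tissue voxels (white matter
#' and cerebrospinal fluid in real data). Each noise-mask voxel time series is
#' linearly detrended and variance-normalized; the returned columns are the
#' top-`k` principal component time courses of the resulting voxel-by-time
#' matrix, ordered by singular value, each unit-norm with the first nonzero
#' element positive.
#'
#' @param v A [vol4d()] volume.
#' @param noise_mask Linear voxel indices (or a logical array on the grid)
#'   marking noise tissue.
#' @param k Number of components (default 5). `k = 0` returns a T x 0 matrix.
#' @return T x k matrix of component time courses, columns `compcor1..k`. If
#'   the mask supports fewer than `k` components, the available ones are
#'   returned with a warning.
#' @export
compcor <- function(v, noise_mask, k = 5) {
  if (!is_count(k)) stopf("`k` must be a count")
  T <- n_timepoints(v)
  if (k >= T) stopf("`k` must be smaller than the number of timepoints")
  idx <- mask_indices(noise_mask, grid_dim(v))
  if (length(idx) == 0L) stopf("`noise_mask` is empty")
  if (k == 0L) return(matrix(numeric(0), T, 0))
  X <- vol_matrix(v)[, idx, drop = FALSE]
  # linear detrend + variance normalization per voxel
  tt <- seq_len(T) - (T + 1) / 2
  X <- X - outer(rep(1, T), colMeans(X)) - outer(tt, colSums(tt * X) / sum(tt^2))
  sds <- apply(X, 2, sd)
  ok <- sds > .Machine$double.eps
  X <- sweep(X[, ok, drop = FALSE], 2, sds[ok], "/")
  if (ncol(X) == 0L) stopf("all noise-mask voxels have zero variance")
  sv <- svd(X, nu = min(k, min(dim(X))), nv = 0)
  r <- sum(sv$d > sv$d[1] * 1e-10)
  kk <- min(k, r)
  if (kk < k) warnf("noise mask supports only %d of %d requested components", kk, k)
  comp <- sv$u[, seq_len(kk), drop = FALSE]
  for (j in seq_len(ncol(comp))) {
    nz <- which(abs(comp[, j]) > 0)[1]
    if (!is.na(nz) && comp[nz, j] < 0) comp[, j] <- -comp[, j]
  }
  colnames(comp) <- paste0("compcor", seq_len(ncol(comp)))
  comp
}

mask_indices <- function(mask, grid) {
  if (is.logical(mask)) {
    if (!is.null(dim(mask)) && !all(dim(mask) == grid))
      stopf("logical mask dimensions do not match the grid")
    which(mask)
  } else {
    idx <- as.integer(mask)
    if (length(idx)) check_region(idx, grid, "mask")
    idx
  }
}

#' Assemble the nuisance design matrix
#'
#' Concatenates the Friston-24 motion set, the spike regressors derived from
#' framewise displacement, the CompCor components, a centered linear trend,
#' and an intercept.
#'
#' @param motion T x 6 motion matrix.
#' @param fd Framewise displacement series (for spike placement).
#' @param compcor_cols T x k CompCor component matrix (may have 0 columns).
#' @param fd_thr Scrubbing threshold passed to [scrubbing_regressors()].
#' @return T x K design matrix with unique column labels, class
#'   `nuisance_matrix`.
#' @export
build_nuisance <- function(motion, fd, compcor_cols = NULL, fd_thr = 0.5) {
  motion <- as_motion(motion)
  T <- nrow(motion)
  if (length(fd) != T) stopf("`fd` length does not match motion rows")
  spikes <- scrubbing_regressors(fd, thr = fd_thr)
  if (is.null(compcor_cols)) compcor_cols <- matrix(numeric(0), T, 0)
  if (nrow(compcor_cols) != T) stopf("CompCor rows do not match T")
  trend <- matrix(seq_len(T) - (T + 1) / 2, ncol = 1,
                  dimnames = list(NULL, "trend"))
  design <- cbind(friston24(motion), spikes, compcor_cols, trend,
                  intercept = 1)
  if (ncol(design) >= T) stopf("nuisance design has K=%d >= T=%d columns", ncol(design), T)
  stopifnot(!anyDuplicated(colnames(design)))
  class(design) <- c("nuisance_matrix", class(design))
  design
}

#' Regress nuisance signals out of a volume
#'
#' Replaces every voxel time series by its least-squares residual against the
#' nuisance design. Rank-deficient designs are handled by the pseudoinverse
#' with a warning.
#'
#' @param v A [vol4d()] volume.
#' @param design T x K nuisance design, e.g. from [build_nuisance()].
#' @return The residual volume (a `vol4d`).
#' @export
regress_out <- function(v, design) {
  design <- unclass(design)
  T <- n_timepoints(v)
  if (nrow(design) != T) stopf("design rows (%d) != T (%d)", nrow(design), T)
  Y <- vol_matrix(v)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warnf("nuisance design is rank deficient (rank %d of %d); using pseudoinverse",
          qrd$rank, ncol(design))
    sv <- svd(design)
    pos <- sv$d > sv$d[1] * 1e-10
    coefs <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) %*% Y / sv$d[pos])
    res <- Y - design %*% coefs
  } else {
    res <- qr.resid(qrd, Y)
  }
  matrix_vol(res, v)
}
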