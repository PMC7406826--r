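# Vectorized voxel-wise mediation engine.
#
# For a resample S (subjects drawn with replacement) let P be the residual-
# maker of the covariate block [1, C] on the resampled rows. With
# xt = P x_S and yt = P y_S, the path estimates at voxel v follow from the
# Frisch-Waugh-Lovell closed form:
#   a   = (xt' M_S) / (xt' xt)
#   b   = [ (xt'xt)(Mt' yt) - (xt' M_S)(xt' yt) ] / det
#   c'  = [ (Mt' Mt)(xt' yt) - (xt' M_S)(Mt' yt) ] / det
#   det = (xt'xt)(Mt' Mt) - (xt' M_S)^2,    Mt = P M_S
# Every voxel-dependent quantity is a linear or quadratic form in the fixed
# mediator matrix M, so one scatter vector per draw (for xt and yt) and one
# packed n x n quadratic form turn the whole bootstrap into BLAS matrix
# products across all voxels simultaneously. Resample indices are shared
# across voxels, which preserves the joint spatial structure of the bootstrap
# distribution and makes results independent of voxel order.
#
# The covariate projector, the quadratic forms (Mt' Mt) and the outcome
# scatter (Mt' yt) do not involve the predictor, so a "bootstrap plan" built
# once can be reused across Freedman-Lane permutation passes, where only x
# changes; each pass then costs a single B x n by n x V product.

# Packed symmetric cross-products of the mediator rows: row k holds
# mult_k * M[i_k, ] * M[j_k, ] for i_k <= j_k (mult 2 off-diagonal).
pack_m2 <- function(M) {
  n <- nrow(M)
  ut <- which(upper.tri(diag(n), diag = TRUE))
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  mult <- ifelse(i == j, 1, 2)
  list(m2 = M[i, , drop = FALSE] * M[j, , drop = FALSE] * mult, ut = ut)
}

# Resampling plan: for each draw the subject-space quadratic form
# Q = S' P S, where S is the resample selection matrix and P the residual-
# maker of [1, C] on the resampled rows. Every pass statistic is a form in Q:
#   scatter(P x_S) = Q x,  xt'xt = x' Q x,  xt'yt = x' Q y,  Mt'Mt = M' Q M,
# so one plan (built once) serves the observed pass and every Freedman-Lane
# permutation pass, each costing a single BLAS product. Draw 1 is the
# identity (point estimates); draws 2..B+1 are the bootstrap. Degenerate
# draws (collinear resampled covariates) are redrawn; >10% is an error.
boot_plan <- function(D0, n, B, seed) {
  set.seed(seed)
  ut <- which(upper.tri(diag(n), diag = TRUE))
  idx <- rbind(seq_len(n), matrix(sample.int(n, B * n, replace = TRUE), B, n))
  QV <- matrix(0, (B + 1L) * n, n)   # Q_b stacked vertically
  Qp <- matrix(0, B + 1L, length(ut))
  n_redrawn <- 0L
  b <- 1L
  while (b <= B + 1L) {
    ib <- idx[b, ]
    Db <- D0[ib, , drop = FALSE]
    R <- tryCatch(chol(crossprod(Db)), error = function(e) NULL)
    if (is.null(R)) {
      if ((n_redrawn <- n_redrawn + 1L) > 0.1 * B + 50)
        stopf("more than 10%% of bootstrap draws were degenerate")
      idx[b, ] <- sample.int(n, n, replace = TRUE)
      next
    }
    Pb <- -Db %*% chol2inv(R) %*% t(Db)
    diag(Pb) <- diag(Pb) + 1
    # gather the resample-space form back to subject space
    Qsmall <- rowsum(t(rowsum(Pb, ib)), ib)
    rows <- as.integer(rownames(Qsmall))
    Qfull <- matrix(0, n, n)
    Qfull[rows, rows] <- Qsmall
    QV[((b - 1L) * n + 1L):(b * n), ] <- Qfull
    Qp[b, ] <- Qfull[ut]
    b <- b + 1L
  }
  list(QV = QV, Q = Qp, n = n, B = B, ut = ut, n_redrawn = n_redrawn)
}

# Quantities that depend on the mediator matrix and outcome only
# (reused across permutation passes).
plan_m_products <- function(plan, M, m2, y) {
  U2 <- t(matrix(plan$QV %*% y, plan$n))   # rows: scatter(P_b y_b)
  list(A2 = U2 %*% M,                      # Mt' yt
       DEN = plan$Q %*% m2$m2,             # Mt' Mt
       U2 = U2, Qy = plan$QV %*% y)
}

# Evaluate all path statistics for one predictor vector under a plan.
# Returns (B+1) x V matrices; row 1 is the point estimate.
pass_stats <- function(plan, x, y, mprod, M, need_cp = TRUE) {
  Qx <- matrix(plan$QV %*% x, plan$n)      # column b holds Q_b x
  U1 <- t(Qx)
  sxx <- pmax(colSums(Qx * x), .Machine$double.eps)
  sxy <- colSums(matrix(mprod$Qy, plan$n) * x)
  A1 <- U1 %*% M
  a <- A1 / sxx
  det <- sxx * mprod$DEN - A1^2
  det[det <= 0] <- NA_real_
  b_ <- (sxx * mprod$A2 - A1 * sxy) / det
  out <- list(a = a, b = b_, ab = a * b_, c = sxy / sxx)
  if (need_cp) out$cp <- (mprod$DEN * sxy - A1 * mprod$A2) / det
  out
}

# Vectorized two-tailed bootstrap p-values over voxels (columns of bstat).
boot_pvalue_mat <- function(bstat, theta, flavor) {
  B <- nrow(bstat)
  clamp <- function(p) pmin(1 - 1 / (2 * B), pmax(1 / (2 * B), p))
  q0 <- clamp(colMeans(bstat < 0) + 0.5 * colMeans(bstat == 0))
  th <- matrix(theta, B, length(theta), byrow = TRUE)
  if (flavor == "bc") {
    z0 <- qnorm(clamp(colMeans(bstat < th) + 0.5 * colMeans(bstat == th)))
    w <- qnorm(q0) - 2 * z0
  } else {
    w <- qnorm(q0)
  }
  p <- 2 * pmin(pnorm(w), 1 - pnorm(w))
  pmin(1, pmax(p, 1 / B))
}

# One full pass: point estimates and bootstrap p-values for one predictor.
mediation_pass <- function(plan, x, y, mprod, M, flavor, full = TRUE) {
  st <- pass_stats(plan, x, y, mprod, M, need_cp = full)
  fix <- function(v) { v[!is.finite(v)] <- 0; v }
  pt_ab <- st$ab[1, ]
  degenerate_v <- !is.finite(st$b[1, ])  # mediator without residual variance
  keep <- c("a", "b", "ab", if (full) "cp")
  bs <- lapply(st[keep], function(m) fix(m[-1, , drop = FALSE]))
  out <- list(ab_hat = fix(pt_ab),
              p_ab = boot_pvalue_mat(bs$ab, fix(pt_ab), flavor))
  out$p_ab[degenerate_v] <- 1
  if (full) {
    out$a_hat <- fix(st$a[1, ]); out$b_hat <- fix(st$b[1, ])
    out$cp_hat <- fix(st$cp[1, ]); out$c_hat <- st$c[1]
    out$p_a <- boot_pvalue_mat(bs$a, out$a_hat, flavor)
    out$p_b <- boot_pvalue_mat(bs$b, out$b_hat, flavor)
    out$p_cp <- boot_pvalue_mat(bs$cp, out$cp_hat, flavor)
    out$p_a[degenerate_v] <- 1; out$p_b[degenerate_v] <- 1; out$p_cp[degenerate_v] <- 1
  }
  out
}

#' Voxel-wise mediation with bootstrap inference
#'
#' Fits the three-path mediation model at every in-mask voxel and derives
#' two-tailed bootstrap p-values for the paths `a`, `b`, `a*b` and `c_prime`.
#' Bootstrap resample indices are shared across voxels (derived from
#' `rng_seed` alone), so results do not depend on voxel order and the joint
#' spatial structure of the bootstrap distribution is preserved.
#'
#' @param input A [mediation_input()].
#' @param B Bootstrap resamples per voxel (default 10000).
#' @param rng_seed Integer seed.
#' @param flavor Bootstrap p-value flavor, `"bc"` (default) or `"percentile"`.
#' @param standardize If `TRUE`, z-score x, y and every mediator column first.
#' @return A `mediation_maps` object: per-voxel coefficient vectors `a`, `b`,
#'   `ab`, `c_prime`, the scalar total effect `c`, p-value vectors `p_a`,
#'   `p_b`, `p_ab`, `p_c_prime`, plus metadata (`B`, `rng_seed`, `flavor`,
#'   `grid`, `mask`).
#' @export
voxelwise_mediation <- function(input, B = 10000, rng_seed = 1,
                                flavor = c("bc", "percentile"),
                                standardize = FALSE) {
  flavor <- match.arg(flavor)
  if (!inherits(input, "mediation_input")) stopf("`input` must be a mediation_input")
  if (!is_count(B) || B < 100) stopf("`B` must be a count >= 100")
  x <- input$x; y <- input$y; M <- input$m
  if (standardize) {
    x <- as.numeric(scale(x)); y <- as.numeric(scale(y)); M <- scale(M)
    M[, attr(M, "scaled:scale") == 0] <- 0
    M <- matrix(as.numeric(M), nrow(input$m), ncol(input$m))
  }
  D0 <- cbind(1, input$covariates)
  m2 <- pack_m2(M)
  plan <- boot_plan(D0, length(x), B, substream_seed(rng_seed, 0L))
  mprod <- plan_m_products(plan, M, m2, y)
  pass <- mediation_pass(plan, x, y, mprod, M, flavor, full = TRUE)
  structure(list(a = pass$a_hat, b = pass$b_hat, ab = pass$ab_hat,
                 c_prime = pass$cp_hat, c = pass$c_hat,
                 p_a = pass$p_a, p_b = pass$p_b, p_ab = pass$p_ab,
                 p_c_prime = pass$p_cp,
                 n_redrawn = plan$n_redrawn,
                 B = as.integer(B), rng_seed = as.integer(rng_seed),
                 flavor = flavor, standardized = standardize,
                 grid = input$grid, mask = input$mask,
                 n_subjects = length(x)),
            class = "mediation_maps")
}

#' @export
print.mediation_maps <- function(x, ...) {
  cat(sprintf("<mediation_maps> %d voxels, %d subjects, B=%d (%s bootstrap)\n",
              length(x$ab), x$n_subjects, x$B, x$flavor))
  cat(sprintf("  ab range [%.3g, %.3g]; min p_ab = %.4g\n",
              min(x$ab), max(x$ab), min(x$p_ab)))
  invisible(x)
}

#' Reassemble a per-voxel vector into its 3D map
#'
#' @param maps A `mediation_maps` object with `grid` metadata.
#' @param what Which component to expand (e.g. `"ab"`, `"p_ab"`).
#' @return 3D array (NA outside the mask).
#' @export
map_array <- function(maps, what = "ab") {
  if (is.null(maps$grid)) stopf("maps carry no grid geometry")
  out <- array(NA_real_, maps$grid)
  out[maps$mask] <- maps[[what]]
  out
}
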