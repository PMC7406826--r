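#' Bundle the inputs of a voxel-wise mediation analysis
#'
#' Joins the behavioural table with the subjects-by-voxels mediator matrix
#' (Fisher-z connectivity) and validates the model invariants: aligned rows,
#' no missing values, and enough subjects to identify the path model with its
#' covariates.
#'
#' @param data Data frame with one row per subject, containing the predictor,
#'   outcome and covariate columns.
#' @param m Subjects x voxels mediator matrix, rows aligned with `data`.
#' @param x,y Column names of the predictor (e.g. acceptance, AAQ-II) and the
#'   outcome (e.g. symptom severity, CAPS-5).
#' @param covariates Character vector of covariate column names (may be empty).
#' @param grid Optional length-3 grid dimensions of the maps.
#' @param mask Optional linear voxel indices of the mediator columns in the
#'   grid (defaults to `1:ncol(m)`).
#' @return An object of class `mediation_input`.
#' @export
mediation_input <- function(data, m, x = "aaq", y = "caps",
                            covariates = c("age", "sex", "bdi", "des"),
                            grid = NULL, mask = NULL) {
  data <- as.data.frame(data)
  for (col in c(x, y, covariates))
    if (!col %in% names(data)) stopf("column `%s` is missing from `data`", col)
  m <- as.matrix(m)
  if (nrow(m) != nrow(data))
    stopf("mediator rows (%d) do not match subjects (%d)", nrow(m), nrow(data))
  vars <- data[, c(x, y, covariates), drop = FALSE]
  if (!all(complete.cases(vars)) || !all(is.finite(m)))
    stopf("mediation inputs must not contain missing values")
  q <- length(covariates)
  if (nrow(data) <= q + 3L)
    stopf("need more than %d subjects for %d covariates", q + 3L, q)
  C <- if (q) as.matrix(vars[, covariates, drop = FALSE]) else NULL
  if (is.null(mask)) mask <- seq_len(ncol(m))
  structure(list(x = as.numeric(vars[[x]]), y = as.numeric(vars[[y]]),
                 m = m, covariates = C, covariate_labels = covariates,
                 grid = grid, mask = as.integer(mask),
                 subject_id = if ("id" %in% names(data)) as.character(data$id)
                              else as.character(seq_len(nrow(data)))),
            class = "mediation_input")
}

# OLS via QR, returning coefficients and standard errors; pseudoinverse with
# a warning for rank-deficient designs.
ols_fit <- function(X, y) {
  qrx <- qr(X)
  n <- nrow(X); p <- ncol(X)
  if (qrx$rank < p) {
    warnf("collinear design (rank %d of %d); using pseudoinverse", qrx$rank, p)
    sv <- svd(X)
    pos <- sv$d > sv$d[1] * 1e-10
    coefs <- sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    res <- y - X %*% coefs
    sigma2 <- sum(res^2) / max(1, n - qrx$rank)
    covb <- sv$v[, pos, drop = FALSE] %*% (t(sv$v[, pos, drop = FALSE]) / sv$d[pos]^2) * sigma2
    list(coef = drop(coefs), se = sqrt(pmax(0, diag(covb))))
  } else {
    coefs <- qr.coef(qrx, y)
    res <- qr.resid(qrx, y)
    sigma2 <- sum(res^2) / (n - p)
    XtXinv <- chol2inv(qr.R(qrx))
    list(coef = coefs, se = sqrt(pmax(0, diag(XtXinv) * sigma2)))
  }
}

#' Fit the three-path mediation model at one voxel
#'
#' Point estimates of the path model: `a` from the mediator regressed on the
#' predictor and covariates; `b` and the direct effect `c_prime` from the
#' outcome regressed on predictor, mediator and covariates; the total effect
#' `c` from the outcome regressed on predictor and covariates. Covariates
#' enter all three regressions, which makes `a * b + c_prime = c` an exact
#' algebraic identity of least squares.
#'
#' @param x Predictor scores (one per subject).
#' @param m Mediator values at one voxel.
#' @param y Outcome scores.
#' @param covariates Optional numeric matrix of covariates.
#' @param standardize If `TRUE`, x, m and y are z-scored first, so paths are
#'   on the correlation scale.
#' @return A `path_fit` object: coefficients `a`, `b`, `c`, `c_prime`,
#'   `ab = a * b`, standard errors of `a` and `b`, and (after
#'   [bootstrap_paths()]) bootstrap p-values.
#' @export
fit_paths <- function(x, m, y, covariates = NULL, standardize = FALSE) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stopf("x, m and y must have equal length")
  check_finite(c(x, m, y), "mediation data")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stopf("covariate rows do not match n")
  }
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= q + 3L) stopf("need more than %d observations for %d covariates", q + 3L, q)
  if (standardize) {
    x <- as.numeric(scale(x)); m <- as.numeric(scale(m)); y <- as.numeric(scale(y))
  }
  D <- cbind(1, x, covariates)
  fa <- ols_fit(D, m)
  fy <- ols_fit(cbind(1, x, m, covariates), y)
  fc <- ols_fit(D, y)
  a <- unname(fa$coef[2]); b <- unname(fy$coef[3]); c_prime <- unname(fy$coef[2])
  structure(list(a = a, b = b, c = unname(fc$coef[2]), c_prime = c_prime,
                 ab = a * b, se_a = unname(fa$se[2]), se_b = unname(fy$se[3]),
                 n = n, n_covariates = q, standardized = standardize,
                 p_a = NA_real_, p_b = NA_real_, p_ab = NA_real_,
                 p_c_prime = NA_real_, B = NA_integer_, flavor = NA_character_,
                 n_redrawn = NA_integer_),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("<path_fit> three-path mediation model\n")
  cat(sprintf("  a = %.4f (se %.4f)   b = %.4f (se %.4f)\n", x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("  ab = %.4f   c' = %.4f   c = %.4f\n", x$ab, x$c_prime, x$c))
  if (!is.na(x$p_ab))
    cat(sprintf("  bootstrap (%s, B=%d): p_a=%.4g p_b=%.4g p_ab=%.4g p_c'=%.4g\n",
                x$flavor, x$B, x$p_a, x$p_b, x$p_ab, x$p_c_prime))
  invisible(x)
}

# Two-tailed bootstrap p-value from the bootstrap distribution of a statistic.
# "bc": bias-corrected percentile inversion; "percentile": plain inversion.
# Floored at 1/B so downstream log transforms stay finite.
boot_pvalue <- function(bstat, theta_hat, flavor = c("bc", "percentile")) {
  flavor <- match.arg(flavor)
  B <- length(bstat)
  clamp <- function(p) pmin(1 - 1 / (2 * B), pmax(1 / (2 * B), p))
  q0 <- clamp(mean(bstat < 0) + 0.5 * mean(bstat == 0))
  if (flavor == "bc") {
    z0 <- qnorm(clamp(mean(bstat < theta_hat) + 0.5 * mean(bstat == theta_hat)))
    w <- qnorm(q0) - 2 * z0
  } else {
    w <- qnorm(q0)
  }
  p <- 2 * min(pnorm(w), 1 - pnorm(w))
  min(1, max(p, 1 / B))
}

#' Bootstrap inference for the mediation paths at one voxel
#'
#' Resamples subjects with replacement `B` times, refits all paths per draw,
#' and returns two-tailed bias-corrected (default) bootstrap p-values for
#' `a`, `b`, `a*b` and `c_prime`. Degenerate draws (a resample in which the
#' design is collinear) are redrawn and counted; more than 10% degenerate
#' draws is an error.
#'
#' @inheritParams fit_paths
#' @param B Number of bootstrap resamples (default 10000, minimum 100).
#' @param rng_seed Integer seed; identical seeds give identical p-values.
#' @param flavor `"bc"` (bias-corrected, default) or `"percentile"`.
#' @return A `path_fit` with bootstrap p-values filled in.
#' @export
bootstrap_paths <- function(x, m, y, covariates = NULL, B = 10000,
                            rng_seed = 1, flavor = c("bc", "percentile"),
                            standardize = FALSE) {
  flavor <- match.arg(flavor)
  if (!is_count(B) || B < 100) stopf("`B` must be a count >= 100")
  fit <- fit_paths(x, m, y, covariates, standardize = standardize)
  if (standardize) {
    x <- as.numeric(scale(x)); m <- as.numeric(scale(m)); y <- as.numeric(scale(y))
  }
  n <- length(x)
  Cmat <- if (is.null(covariates)) NULL else as.matrix(covariates)
  set.seed(rng_seed)
  bstat <- matrix(NA_real_, B, 4)  # a, b, ab, c_prime
  n_redrawn <- 0L
  b_i <- 1L
  max_attempts <- ceiling(B * 1.1) + 50L
  attempts <- 0L
  while (b_i <= B) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stopf("more than 10%% of bootstrap draws were degenerate (%d redraws)", n_redrawn)
    idx <- sample.int(n, n, replace = TRUE)
    D <- cbind(1, x[idx], if (!is.null(Cmat)) Cmat[idx, , drop = FALSE])
    Dy <- cbind(D[, 1:2, drop = FALSE], m[idx],
                if (!is.null(Cmat)) Cmat[idx, , drop = FALSE])
    qa <- qr(D); qy <- qr(Dy)
    if (qa$rank < ncol(D) || qy$rank < ncol(Dy)) { n_redrawn <- n_redrawn + 1L; next }
    ca <- qr.coef(qa, m[idx]); cy <- qr.coef(qy, y[idx]); cc <- qr.coef(qa, y[idx])
    bstat[b_i, ] <- c(ca[2], cy[3], ca[2] * cy[3], cy[2])
    b_i <- b_i + 1L
  }
  fit$p_a <- boot_pvalue(bstat[, 1], fit$a, flavor)
  fit$p_b <- boot_pvalue(bstat[, 2], fit$b, flavor)
  fit$p_ab <- boot_pvalue(bstat[, 3], fit$ab, flavor)
  fit$p_c_prime <- boot_pvalue(bstat[, 4], fit$c_prime, flavor)
  fit$B <- as.integer(B)
  fit$flavor <- flavor
  fit$n_redrawn <- n_redrawn
  fit
}
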