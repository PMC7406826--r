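#' Pearson correlation with t-based p-value
#'
#' @param u,v Numeric vectors of equal length (>= 3), nonzero variance.
#' @return One-row tibble: `estimate` (r), `statistic` (t), `p.value`
#'   (two-tailed), `n`.
#' @export
pearson_test <- function(u, v) {
  if (length(u) != length(v)) stopf("`u` and `v` must have equal length")
  n <- length(u)
  if (n < 3) stopf("need at least 3 observations")
  check_finite(c(u, v), "input")
  if (sd(u) <= .Machine$double.eps || sd(v) <= .Machine$double.eps)
    stopf("zero variance input")
  r <- cor(u, v)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  tibble(estimate = r, statistic = tstat,
         p.value = min(1, 2 * pt(-abs(tstat), df = n - 2)), n = n)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the least-squares residuals of `u` and `v` on the
#' covariates (plus intercept); the p-value uses a t reference with
#' `n - q - 2` degrees of freedom. With no covariates this reduces exactly to
#' [pearson_test()].
#'
#' @param u,v Numeric vectors.
#' @param covariates Numeric matrix (n x q) or NULL.
#' @return One-row tibble: `estimate`, `statistic`, `p.value`, `n`, `df`.
#' @export
partial_correlation <- function(u, v, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(dplyr::mutate(pearson_test(u, v), df = length(u) - 2L))
  Cmat <- as.matrix(covariates)
  n <- length(u); q <- ncol(Cmat)
  if (nrow(Cmat) != n || length(v) != n) stopf("inputs must have equal row counts")
  if (n <= q + 2) stopf("need more than q + 2 = %d observations", q + 2)
  D <- cbind(1, Cmat)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) warnf("collinear covariates; effective rank %d", qrd$rank)
  ru <- qr.resid(qrd, u); rv <- qr.resid(qrd, v)
  if (sd(ru) <= .Machine$double.eps || sd(rv) <= .Machine$double.eps)
    stopf("zero residual variance after removing covariates")
  r <- cor(ru, rv)
  df <- n - q - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  tibble(estimate = r, statistic = tstat,
         p.value = min(1, 2 * pt(-abs(tstat), df = df)), n = n, df = df)
}

#' Pooled-variance two-sample t-test
#'
#' @param g1,g2 Numeric vectors, each with at least 2 observations.
#' @return One-row tibble: `statistic` (t for `g1 - g2`), `p.value`
#'   (two-tailed), `df`, group means.
#' @export
two_sample_t <- function(g1, g2) {
  if (length(g1) < 2 || length(g2) < 2) stopf("each group needs at least 2 observations")
  check_finite(c(g1, g2), "input")
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  if (sp2 <= .Machine$double.eps) {
    tstat <- 0
  } else {
    tstat <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  tibble(statistic = tstat, p.value = min(1, 2 * pt(-abs(tstat), df = n1 + n2 - 2)),
         df = n1 + n2 - 2, mean1 = mean(g1), mean2 = mean(g2))
}

power_corr_matrix <- function(r_xm, r_my, r_xy, input = c("correlations", "paths")) {
  input <- match.arg(input)
  if (input == "paths") {
    # r_xm, r_my, r_xy read as standardized coefficients a, b, c'
    a <- r_xm; b <- r_my; cp <- r_xy
    r_xy_imp <- cp + a * b
    r_my_imp <- b + a * cp
    S <- matrix(c(1, a, r_xy_imp, a, 1, r_my_imp, r_xy_imp, r_my_imp, 1), 3, 3)
  } else {
    S <- matrix(c(1, r_xm, r_xy, r_xm, 1, r_my, r_xy, r_my, 1), 3, 3)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stopf("correlations (r_xm=%.3g, r_my=%.3g, r_xy=%.3g) do not form a positive definite matrix",
          r_xm, r_my, r_xy)
  S
}

#' Monte Carlo power analysis for the indirect effect
#'
#' Estimates the power of the Monte-Carlo confidence-interval test of the
#' indirect effect `a*b` in a simple three-variable mediation model. Per
#' replication, `n` observations are drawn from the trivariate normal implied
#' by the input correlations; `M ~ X` and `Y ~ X + M` are fit by least
#' squares; `n_mc_draws` pairs `(a*, b*)` are drawn from independent normals
#' centred at the estimates with the fitted standard errors; the replication
#' succeeds when the equal-tail `ci_level` interval of `a* b*` excludes zero.
#' Power is the success fraction.
#'
#' @param n Sample size per replication (>= 5).
#' @param r_xm,r_my,r_xy Input correlations (X,M), (M,Y), (X,Y); with
#'   `input = "paths"` they are read instead as standardized coefficients
#'   a, b, c' and the implied correlation matrix is used.
#' @param sds Standard deviations of X, M, Y (default all 1; power is
#'   invariant to them).
#' @param n_reps Number of replications (default 1000).
#' @param n_mc_draws Monte Carlo draws per replication (default 20000).
#' @param ci_level Confidence level (default 0.95).
#' @param rng_seed Integer seed.
#' @param input Interpretation of the three coefficients; see above.
#' @return An `mc_power` object: `power`, `mc_se` (binomial standard error),
#'   and the settings. `tidy()` turns it into a one-row tibble.
#' @examples
#' mc_power_indirect(n = 33, n_reps = 200, rng_seed = 1)
#' @export
mc_power_indirect <- function(n = 33, r_xm = 0.65, r_my = 0.65, r_xy = 0.60,
                              sds = c(1, 1, 1), n_reps = 1000,
                              n_mc_draws = 20000, ci_level = 0.95,
                              rng_seed = 1, input = c("correlations", "paths")) {
  input <- match.arg(input)
  if (!is_count(n) || n < 5) stopf("`n` must be a count >= 5")
  if (!is_count(n_reps) || n_reps < 1) stopf("`n_reps` must be a positive count")
  if (any(sds <= 0) || length(sds) != 3) stopf("`sds` must be 3 positive values")
  if (ci_level <= 0 || ci_level >= 1) stopf("`ci_level` must be in (0, 1)")
  S <- power_corr_matrix(r_xm, r_my, r_xy, input)
  L <- chol(S * tcrossprod(sds))
  alpha2 <- (1 - ci_level) / 2
  set.seed(rng_seed)
  success <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    Z <- matrix(rnorm(n * 3), n, 3) %*% L
    x <- Z[, 1]; m <- Z[, 2]; y <- Z[, 3]
    fa <- ols_fit(cbind(1, x), m)
    fy <- ols_fit(cbind(1, x, m), y)
    ab <- rnorm(n_mc_draws, fa$coef[2], fa$se[2]) *
      rnorm(n_mc_draws, fy$coef[3], fy$se[3])
    ci <- quantile(ab, c(alpha2, 1 - alpha2), names = FALSE, type = 7)
    success[i] <- ci[1] > 0 || ci[2] < 0
  }
  p <- mean(success)
  structure(list(power = p, mc_se = sqrt(p * (1 - p) / n_reps), n = n,
                 r_xm = r_xm, r_my = r_my, r_xy = r_xy, sds = sds,
                 n_reps = n_reps, n_mc_draws = n_mc_draws,
                 ci_level = ci_level, rng_seed = rng_seed, input = input),
            class = "mc_power")
}

#' @export
print.mc_power <- function(x, ...) {
  cat(sprintf("<mc_power> power = %.3f (MC se %.3f) at n = %d\n",
              x$power, x$mc_se, x$n))
  cat(sprintf("  correlations: r_xm=%.2f r_my=%.2f r_xy=%.2f; %d reps x %d draws\n",
              x$r_xm, x$r_my, x$r_xy, x$n_reps, x$n_mc_draws))
  invisible(x)
}

#' Power curve over sample sizes
#'
#' Runs [mc_power_indirect()] for each sample size and returns a tibble.
#'
#' @param n_values Integer vector of sample sizes.
#' @param ... Passed to [mc_power_indirect()].
#' @param rng_seed Base seed; each sample size gets its own substream.
#' @return Tibble with columns `n`, `power`, `mc_se` (class `power_curve`).
#' @export
power_curve <- function(n_values, ..., rng_seed = 1) {
  out <- purrr::map_dfr(n_values, function(nn) {
    fit <- mc_power_indirect(n = nn, ..., rng_seed = substream_seed(rng_seed, nn))
    tibble(n = nn, power = fit$power, mc_se = fit$mc_se)
  })
  class(out) <- c("power_curve", class(out))
  out
}
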