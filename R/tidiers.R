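#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted path model
#'
#' @param x A `path_fit` from [fit_paths()] or [bootstrap_paths()].
#' @param ... Unused.
#' @return Tibble with one row per path (`a`, `b`, `c`, `c_prime`, `ab`):
#'   `term`, `estimate`, `std.error` (where defined), `p.value` (bootstrap,
#'   where computed).
#' @method tidy path_fit
#' @export
tidy.path_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c", "c_prime", "ab"),
         estimate = c(x$a, x$b, x$c, x$c_prime, x$ab),
         std.error = c(x$se_a, x$se_b, NA, NA, NA),
         p.value = c(x$p_a, x$p_b, NA, x$p_c_prime, x$p_ab))
}

#' @rdname tidy.path_fit
#' @method glance path_fit
#' @export
glance.path_fit <- function(x, ...) {
  tibble(nobs = x$n, n_covariates = x$n_covariates, B = x$B,
         flavor = x$flavor, standardized = x$standardized,
         n_redrawn = x$n_redrawn)
}

#' Tidy a Monte Carlo power estimate
#'
#' @param x An `mc_power` object.
#' @param ... Unused.
#' @return One-row tibble: `power`, `mc_se`, `n`, the input correlations and
#'   replication settings.
#' @method tidy mc_power
#' @export
tidy.mc_power <- function(x, ...) {
  tibble(power = x$power, mc_se = x$mc_se, n = x$n,
         r_xm = x$r_xm, r_my = x$r_my, r_xy = x$r_xy,
         n_reps = x$n_reps, n_mc_draws = x$n_mc_draws, ci_level = x$ci_level)
}

#' Tidy a cluster inference result
#'
#' @param x A `cluster_result` (including [cluster_fwe()] output).
#' @param ... Unused.
#' @return The cluster table as a tibble.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) as_tibble(x$clusters)

#' @rdname tidy.cluster_result
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_perm = attr(x, "n_perm") %||% NA_integer_,
         B = attr(x, "B") %||% NA_integer_,
         alpha_primary = attr(x, "alpha_primary") %||% NA_real_,
         connectivity = attr(x, "connectivity") %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
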