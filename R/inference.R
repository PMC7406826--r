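#' Primary voxel threshold
#'
#' Marks voxels whose (already two-tailed) p-value lies strictly below the
#' primary threshold.
#'
#' @param p_map Numeric vector or array of p-values.
#' @param alpha Primary threshold (default 0.001); the boundary value itself
#'   is excluded.
#' @return Logical object of the same shape.
#' @export
primary_threshold <- function(p_map, alpha = 0.001) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) stopf("`alpha` must be in (0, 1]")
  out <- p_map < alpha
  out[is.na(p_map)] <- FALSE
  out
}

neighbor_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L)) stopf("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Connected components of a binary map
#'
#' Maximal connected sets of supra-threshold voxels under the chosen 3D
#' neighbourhood (6 = faces, 18 = faces and edges, 26 = full). Cluster labels
#' are deterministic: descending size, ties broken by the lexicographically
#' smallest peak voxel.
#'
#' @param binary 3D logical array.
#' @param connectivity 6, 18 or 26 (default 18).
#' @param stat Optional 3D array used to locate each cluster's peak (largest
#'   `|stat|`); defaults to the first voxel in array order.
#' @param voxel_size Voxel size in mm for peak coordinates (default 1 mm).
#' @return A `cluster_result`: `label_map` (3D integer array, 0 = background)
#'   and `clusters`, a tibble with `label`, `size`, `peak_x/y/z` (voxel
#'   indices) and `peak_mm_x/y/z`.
#' @export
connected_components <- function(binary, connectivity = 18, stat = NULL,
                                 voxel_size = c(1, 1, 1)) {
  if (!is.logical(binary) || length(dim(binary)) != 3L)
    stopf("`binary` must be a 3D logical array")
  grid <- dim(binary)
  off <- neighbor_offsets(as.integer(connectivity))
  labels <- array(0L, grid)
  supra <- which(binary)
  comp_of <- integer(length(supra))
  pos <- array(0L, grid); pos[supra] <- seq_along(supra)
  coords <- voxel_coords(supra, grid)
  ncomp <- 0L
  for (s in seq_along(supra)) {
    if (comp_of[s]) next
    ncomp <- ncomp + 1L
    queue <- s; comp_of[s] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      cc <- coords[cur, ]
      nb <- sweep(off, 2, cc, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= grid[1] & nb[, 2] >= 1 & nb[, 2] <= grid[2] &
        nb[, 3] >= 1 & nb[, 3] <= grid[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * grid[1] + (nb[, 3] - 1L) * grid[1] * grid[2]
      hit <- pos[lin]
      hit <- hit[hit > 0L]
      new <- hit[comp_of[hit] == 0L]
      comp_of[new] <- ncomp
      queue <- c(queue, new)
    }
  }
  if (ncomp == 0L) {
    return(structure(list(label_map = labels,
                          clusters = tibble(label = integer(0), size = integer(0),
                                            peak_x = integer(0), peak_y = integer(0),
                                            peak_z = integer(0), peak_mm_x = numeric(0),
                                            peak_mm_y = numeric(0), peak_mm_z = numeric(0))),
                     class = "cluster_result"))
  }
  peak_of <- function(k) {
    members <- supra[comp_of == k]
    if (!is.null(stat)) members[which.max(abs(stat[members]))] else min(members)
  }
  info <- tibble(
    comp = seq_len(ncomp),
    size = as.integer(tabulate(comp_of, ncomp)),
    peak = vapply(seq_len(ncomp), peak_of, integer(1)))
  ord <- order(-info$size, info$peak)
  info <- info[ord, ]
  relabel <- integer(ncomp); relabel[info$comp] <- seq_len(ncomp)
  labels[supra] <- relabel[comp_of]
  pk <- voxel_coords(info$peak, grid)
  clusters <- tibble(label = seq_len(ncomp), size = info$size,
                     peak_x = pk[, 1], peak_y = pk[, 2], peak_z = pk[, 3],
                     peak_mm_x = (pk[, 1] - 1) * voxel_size[1],
                     peak_mm_y = (pk[, 2] - 1) * voxel_size[2],
                     peak_mm_z = (pk[, 3] - 1) * voxel_size[3])
  structure(list(label_map = labels, clusters = clusters), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s)\n", nrow(x$clusters)))
  print(x$clusters)
  invisible(x)
}

# Sign-homogeneous supra-threshold clustering of an ab map: positive and
# negative effects are clustered separately, then merged into one result.
signed_clusters <- function(p_ab, ab, grid, mask, alpha, connectivity, voxel_size) {
  supra <- primary_threshold(p_ab, alpha)
  stat_map <- array(0, grid); stat_map[mask] <- ab
  out <- NULL
  for (sgn in c(1, -1)) {
    bin <- array(FALSE, grid)
    bin[mask] <- supra & (sign(ab) == sgn)
    cl <- connected_components(bin, connectivity, stat = stat_map, voxel_size = voxel_size)
    cl$clusters$sign <- if (nrow(cl$clusters)) sgn else numeric(0)
    out <- if (is.null(out)) list(cl) else c(out, list(cl))
  }
  out
}

max_cluster_size <- function(cl_list) {
  sizes <- unlist(lapply(cl_list, function(cl) cl$clusters$size))
  if (length(sizes)) max(sizes) else 0L
}

#' Cluster-extent family-wise error correction by subject permutation
#'
#' Builds the null distribution of the maximum supra-threshold cluster size by
#' permuting the predictor across subjects (covariates handled by the
#' Freedman-Lane scheme: the residuals of X on the covariates are permuted and
#' the fitted part re-added), re-running the voxel-wise `a*b` bootstrap test
#' for every permutation with the same settings as the observed pass, and
#' recording the maximum cluster size over the sign-split supra-threshold
#' maps. The corrected p-value of an observed cluster of size `s` is
#' `(1 + #\{perm max >= s\}) / (1 + n_perm)`.
#'
#' @param input A [mediation_input()] with `grid` geometry.
#' @param B Bootstrap resamples per voxel for both the observed and the
#'   permutation passes (default 10000). At desk scale pair a reduced `B`
#'   with an `alpha_primary` above the p-value floor `1/B`.
#' @param n_perm Number of permutations (default 1000; below 100 a warning).
#' @param alpha_primary Primary voxel threshold on the two-tailed `p_ab` map
#'   (default 0.001).
#' @param connectivity Cluster neighbourhood, 6, 18 (default) or 26.
#' @param rng_seed Integer seed governing bootstraps and permutations.
#' @param flavor Bootstrap p-value flavor (`"bc"` or `"percentile"`).
#' @param voxel_size Voxel size in mm for peak coordinates.
#' @return A `cluster_result` whose `clusters` tibble gains `sign`,
#'   `corrected_p`, and the cluster-mean path coefficients `mean_a`, `mean_b`,
#'   `mean_ab`; metadata in attributes.
#' @export
cluster_fwe <- function(input, B = 10000, n_perm = 1000, alpha_primary = 0.001,
                        connectivity = 18, rng_seed = 1,
                        flavor = c("bc", "percentile"),
                        voxel_size = c(1, 1, 1)) {
  flavor <- match.arg(flavor)
  if (!inherits(input, "mediation_input")) stopf("`input` must be a mediation_input")
  if (is.null(input$grid)) stopf("`input` must carry grid geometry for clustering")
  if (!is_count(n_perm) || n_perm < 1) stopf("`n_perm` must be a positive count")
  if (n_perm < 100) warnf("n_perm = %d gives a coarse null; 100+ recommended", n_perm)
  if (alpha_primary <= 1 / B)
    warnf("alpha_primary = %g is at or below the bootstrap p floor 1/B = %g; no voxel can pass",
          alpha_primary, 1 / B)
  grid <- input$grid; mask <- input$mask
  n <- length(input$x)
  M <- input$m
  D0 <- cbind(1, input$covariates)
  m2 <- pack_m2(M)
  # One resampling plan is shared by the observed pass and every permutation
  # pass: the same statistic map is applied to each relabelling, so the
  # permutation p-values inherit exact exchangeability. The plan seed matches
  # voxelwise_mediation(), making the observed maps identical to a standalone
  # run at the same B, seed and flavor.
  plan <- boot_plan(D0, n, B, substream_seed(rng_seed, 0L))
  mprod <- plan_m_products(plan, M, m2, input$y)
  obs_pass <- mediation_pass(plan, input$x, input$y, mprod, M, flavor, full = TRUE)
  maps <- structure(list(a = obs_pass$a_hat, b = obs_pass$b_hat,
                         ab = obs_pass$ab_hat, c_prime = obs_pass$cp_hat,
                         c = obs_pass$c_hat, p_a = obs_pass$p_a,
                         p_b = obs_pass$p_b, p_ab = obs_pass$p_ab,
                         p_c_prime = obs_pass$p_cp,
                         n_redrawn = plan$n_redrawn, B = as.integer(B),
                         rng_seed = as.integer(rng_seed), flavor = flavor,
                         standardized = FALSE, grid = grid, mask = mask,
                         n_subjects = n),
                    class = "mediation_maps")
  obs <- signed_clusters(maps$p_ab, maps$ab, grid, mask, alpha_primary,
                         connectivity, voxel_size)

  # Freedman-Lane decomposition of the predictor
  qrd <- qr(D0)
  xhat <- qr.fitted(qrd, input$x)
  xres <- qr.resid(qrd, input$x)
  null_max <- integer(n_perm)
  set.seed(substream_seed(rng_seed, 777000L))
  perms <- replicate(n_perm, sample.int(n, n), simplify = FALSE)
  for (j in seq_len(n_perm)) {
    xj <- xhat + xres[perms[[j]]]
    pass <- mediation_pass(plan, xj, input$y, mprod, M, flavor, full = FALSE)
    cls <- signed_clusters(pass$p_ab, pass$ab_hat, grid, mask, alpha_primary,
                           connectivity, voxel_size)
    null_max[j] <- max_cluster_size(cls)
  }

  merged <- NULL
  for (k in seq_along(obs)) {
    cl <- obs[[k]]
    tab <- cl$clusters
    if (!nrow(tab)) next
    tab$corrected_p <- vapply(tab$size, function(s)
      (1 + sum(null_max >= s)) / (1 + n_perm), numeric(1))
    lm_ <- cl$label_map
    for (stat_name in c("a", "b", "ab")) {
      full <- array(NA_real_, grid); full[mask] <- maps[[stat_name]]
      tab[[paste0("mean_", stat_name)]] <-
        vapply(tab$label, function(l) mean(full[lm_ == l], na.rm = TRUE), numeric(1))
    }
    merged <- if (is.null(merged)) tab else rbind(merged, tab)
  }
  label_map <- array(0L, grid)
  if (!is.null(merged)) {
    merged <- merged[order(-merged$size, merged$peak_x, merged$peak_y, merged$peak_z), ]
    new_label <- seq_len(nrow(merged))
    for (i in new_label) {
      src <- if (merged$sign[i] > 0) obs[[1]] else obs[[2]]
      label_map[src$label_map == merged$label[i] &
                  (label_map == 0L)] <- i
    }
    merged$label <- new_label
  } else {
    merged <- tibble(label = integer(0), size = integer(0),
                     peak_x = integer(0), peak_y = integer(0), peak_z = integer(0),
                     peak_mm_x = numeric(0), peak_mm_y = numeric(0),
                     peak_mm_z = numeric(0), sign = numeric(0),
                     corrected_p = numeric(0), mean_a = numeric(0),
                     mean_b = numeric(0), mean_ab = numeric(0))
  }
  structure(list(label_map = label_map, clusters = as_tibble(merged),
                 null_max = null_max, maps = maps),
            class = c("fwe_result", "cluster_result"),
            n_perm = n_perm, B = B, alpha_primary = alpha_primary,
            connectivity = connectivity, rng_seed = rng_seed)
}
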