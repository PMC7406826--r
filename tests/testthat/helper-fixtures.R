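# Shared fixture builders. Everything is generated in code; no stored data.

# A small 4D volume from a T x V matrix laid out on a given grid.
vol_from_matrix <- function(m, grid, voxel_size = c(3, 3, 4.5), tr = 2) {
  vol4d(array(t(m), dim = c(grid, nrow(m))), voxel_size = voxel_size, tr = tr)
}

# Single-timeseries volume (1x1x1 grid) for filter tests.
vol_from_series <- function(x, tr = 2) {
  vol4d(array(x, dim = c(1, 1, 1, length(x))), voxel_size = c(3, 3, 4.5), tr = tr)
}

# A tiny cohort specification used across tests.
small_spec <- function(...) {
  cohort_spec(n_subjects = 12, n_volumes = 40, grid = c(10, 10, 5), rng_seed = 7, ...)
}

# Brute-force Pearson correlation straight from the definition.
brute_cor <- function(u, v) {
  n <- length(u)
  su <- sum(u); sv <- sum(v)
  num <- n * sum(u * v) - su * sv
  den <- sqrt(n * sum(u^2) - su^2) * sqrt(n * sum(v^2) - sv^2)
  num / den
}

# Brute-force OLS coefficients via the normal equations.
brute_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Exhaustive flood fill used as the connected-components oracle.
brute_components <- function(binary, connectivity) {
  grid <- dim(binary)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nz <- rowSums(off != 0)
  off <- off[switch(as.character(connectivity),
                    "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1), ]
  labels <- array(0L, grid)
  nxt <- 0L
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) for (k in seq_len(grid[3])) {
    if (!binary[i, j, k] || labels[i, j, k] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j, k))
    labels[i, j, k] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(off))) {
        q <- p + as.integer(off[o, ])
        if (any(q < 1) || any(q > grid)) next
        if (binary[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- nxt
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  labels
}
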