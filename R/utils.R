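#' @importFrom stats cor mvfft pnorm pt qnorm quantile rbinom
#'   rnorm runif sd var complete.cases
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Internal assertion helper: message names the violated condition.
stopf <- function(...) abort(sprintf(...), call = NULL)

warnf <- function(...) warn(sprintf(...))

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("`%s` contains non-finite values", what)
  invisible(x)
}

# Derive a child RNG seed from a base seed and an integer key, staying within
# the 32-bit signed range required by set.seed().
substream_seed <- function(seed, key) {
  s <- (as.double(seed) %% 2147483647) * 69069 + as.double(key) * 12345 + 1
  as.integer(s %% 2147483647)
}

## ---- 4D volume container ---------------------------------------------------

#' Construct a 4D functional volume
#'
#' A light container for a subject's functional image: a numeric array with
#' dimensions `nx x ny x nz x T` (spatial grid first, time last) carrying the
#' voxel size in millimetres and the repetition time in seconds.
#'
#' @param data Numeric 4D array, `nx x ny x nz x T`.
#' @param voxel_size Length-3 numeric, voxel edge lengths in mm.
#' @param tr Repetition time in seconds.
#' @return An object of class `vol4d`.
#' @export
vol4d <- function(data, voxel_size = c(3, 3, 4.5), tr = 2) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stopf("`data` must be a 4D array (nx, ny, nz, T)")
  check_finite(data, "data")
  if (dim(data)[4] < 8L) stopf("volume must have at least 8 timepoints")
  if (!is.numeric(voxel_size) || length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("`voxel_size` must be 3 positive mm values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stopf("`tr` must be > 0")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 tr = as.numeric(tr)),
            class = "vol4d")
}

#' @export
print.vol4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol4d> %d x %d x %d voxels, %d volumes, voxel %s mm, TR %g s\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = "x"), x$tr))
  invisible(x)
}

n_timepoints <- function(v) dim(v$data)[4]
grid_dim <- function(v) dim(v$data)[1:3]

# T x V matrix view of a vol4d (columns are voxel time series).
vol_matrix <- function(v) {
  d <- dim(v$data)
  t(matrix(v$data, nrow = prod(d[1:3]), ncol = d[4]))
}

# Rebuild a vol4d from a T x V matrix and a template volume.
matrix_vol <- function(m, template) {
  d <- dim(template$data)
  new_vol4d(array(t(m), dim = d), template$voxel_size, template$tr)
}

## ---- voxel index helpers ---------------------------------------------------

# Regions are stored as integer vectors of linear voxel indices into the grid.
region_from_box <- function(grid, xr, yr, zr) {
  idx <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
  sort(idx[, 1] + (idx[, 2] - 1L) * grid[1] + (idx[, 3] - 1L) * grid[1] * grid[2])
}

voxel_coords <- function(idx, grid) {
  idx0 <- idx - 1L
  cbind(x = idx0 %% grid[1] + 1L,
        y = (idx0 %/% grid[1]) %% grid[2] + 1L,
        z = idx0 %/% (grid[1] * grid[2]) + 1L)
}

check_region <- function(region, grid, what) {
  if (length(region) == 0L) stopf("`%s` is empty", what)
  if (anyDuplicated(region)) stopf("`%s` has duplicate voxels", what)
  if (any(region < 1L) || any(region > prod(grid)))
    stopf("`%s` falls outside the %s grid", what, paste(grid, collapse = "x"))
  invisible(region)
}

## ---- band-limited noise ----------------------------------------------------

# Ideal-mask band-limiting of the columns of a T x n matrix; retains Fourier
# bins with lo <= f <= hi (inclusive), removes all others including DC.
band_limit <- function(m, tr, lo, hi) {
  m <- as.matrix(m)
  T <- nrow(m)
  f <- fft_freqs(T, tr)
  keep <- f >= lo & f <= hi
  ft <- mvfft(m)
  ft[!keep, ] <- 0
  Re(mvfft(ft, inverse = TRUE)) / T
}

fft_freqs <- function(T, tr) {
  k <- 0:(T - 1)
  pmin(k, T - k) / (T * tr)
}

# Number of Fourier coefficients an ideal band mask keeps (counting +/- bins);
# determines the effective temporal degrees of freedom of band-limited series.
band_bin_count <- function(T, tr, lo, hi) sum(fft_freqs(T, tr) >= lo & fft_freqs(T, tr) <= hi)

# Unit-variance band-limited Gaussian noise, T x n, synthesized directly in
# the frequency domain (complex Gaussian coefficients at the kept bins,
# Hermitian symmetry for a real signal).
band_noise <- function(T, n, tr, lo, hi) {
  f <- (1:(T %/% 2)) / (T * tr)
  kept <- which(f >= lo & f <= hi)
  if (!length(kept)) stopf("band [%g, %g] Hz contains no Fourier bins", lo, hi)
  S <- matrix(0 + 0i, T, n)
  co <- matrix(complex(real = rnorm(length(kept) * n),
                       imaginary = rnorm(length(kept) * n)),
               length(kept), n)
  S[kept + 1L, ] <- co
  S[T + 1L - kept, ] <- Conj(co)
  x <- Re(mvfft(S, inverse = TRUE))
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sweep(x, 2, pmax(sds, .Machine$double.eps), "/")
}

# Internal constructor without validation, for hot paths on known-good data.
new_vol4d <- function(data, voxel_size, tr) {
  structure(list(data = data, voxel_size = voxel_size, tr = tr), class = "vol4d")
}

## ---- Gaussian kernel (shared by smoothing and generator calibration) -------

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
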