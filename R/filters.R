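#' Spatial Gaussian smoothing
#'
#' Separable 3D Gaussian smoothing of every volume, with the kernel width
#' given as full width at half maximum in millimetres and converted to voxels
#' per axis using the stored voxel size. Truncated boundary kernels are
#' renormalized, so a constant image maps exactly to itself and interior
#' voxels see the closed-form kernel.
#'
#' @param v A [vol4d()] volume.
#' @param fwhm Full width at half maximum in mm (default 4); 0 is the identity.
#' @return The smoothed volume.
#' @export
smooth_gaussian <- function(v, fwhm = 4) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm < 0)
    stopf("`fwhm` must be a nonnegative scalar")
  if (fwhm == 0) return(v)
  sig <- fwhm_to_sigma(fwhm) / v$voxel_size
  d <- dim(v$data)
  out <- v$data
  for (ax in 1:3) {
    K <- conv_matrix(gauss_kernel_1d(sig[ax]), d[ax])
    perm <- c(ax, setdiff(1:4, ax))
    arr <- aperm(out, perm)
    m <- matrix(arr, nrow = d[ax])
    arr <- array(K %*% m, dim = dim(arr))
    out <- aperm(arr, order(perm))
  }
  new_vol4d(out, v$voxel_size, v$tr)
}

# Dense 1D convolution matrix with boundary renormalization (rows sum to 1).
conv_matrix <- function(k, n) {
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

#' Temporal band-pass filter
#'
#' Ideal (hard-mask) frequency filtering of every voxel time series: Fourier
#' bins with `lo <= f <= hi` are retained, all others (including the DC
#' component) are zeroed. The operation is linear and exactly testable:
#' in-band sinusoids pass, out-of-band sinusoids and constants are removed.
#'
#' @param v A [vol4d()] volume.
#' @param lo,hi Band edges in Hz (defaults 0.01 and 0.1). `hi` must not exceed
#'   the Nyquist frequency `1 / (2 * tr)`.
#' @return The filtered volume.
#' @export
bandpass_filter <- function(v, lo = 0.01, hi = 0.1) {
  nyq <- 1 / (2 * v$tr)
  if (!(lo >= 0 && lo < hi)) stopf("band edges must satisfy 0 <= lo < hi")
  if (hi > nyq + 1e-12) stopf("`hi` = %g Hz exceeds the Nyquist frequency %g Hz", hi, nyq)
  matrix_vol(band_limit(vol_matrix(v), v$tr, lo, hi), v)
}
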