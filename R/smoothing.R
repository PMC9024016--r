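#' FWHM to Gaussian sigma
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, the neuroimaging convention.
#'
#' @param fwhm full width at half maximum, mm.
#' @return sigma in the same units.
#' @export
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1D discrete Gaussian kernel in voxel units, truncated at 4 sigma,
# normalized to sum 1 over its support.
gaussKernel1d <- function(sigmaVox) {
  radius <- max(1L, floor(4 * sigmaVox))
  x <- seq(-radius, radius)
  k <- exp(-0.5 * (x / sigmaVox)^2)
  k / sum(k)
}

# banded n x n convolution matrix with zero padding (no renormalization at
# the boundary)
convMatrix1d <- function(n, kernel) {
  radius <- (length(kernel) - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (d in seq(-radius, radius)) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    A[cbind(i[ok], j[ok])] <- kernel[d + radius + 1L]
  }
  A
}

applyAlongAxis <- function(arr, A, axis) {
  d <- dim(arr)
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  x <- aperm(arr, perm)
  dp <- dim(x)
  y <- A %*% matrix(x, nrow = dp[1])
  y <- array(as.numeric(y), dim = dp)
  aperm(y, order(perm))
}

#' Separable Gaussian smoothing of a volume
#'
#' Smooths with a separable Gaussian whose per-axis sigma in voxels is
#' `fwhm / (2 sqrt(2 ln 2)) / voxelSize[axis]` (anisotropic voxels are
#' handled per axis). The kernel is truncated at 4 sigma and normalized over
#' its support; the boundary uses zero padding with no renormalization, so
#' mass leaving the field of view is lost, while an impulse at least 4 sigma
#' from every face conserves its sum. Smoothing is linear.
#'
#' @param vol a [ScalarVolume-class].
#' @param fwhm kernel full width at half maximum in mm (> 0).
#' @return A [ScalarVolume-class] on the same grid.
#' @export
gaussianSmooth <- function(vol, fwhm) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0)
    stop("fwhm must be a single positive number (mm)")
  arr <- vol@data
  for (axis in 1:3) {
    sigmaVox <- fwhmToSigma(fwhm) / vol@grid@voxelSize[axis]
    A <- convMatrix1d(vol@grid@shape[axis], gaussKernel1d(sigmaVox))
    arr <- applyAlongAxis(arr, A, axis)
  }
  new("ScalarVolume", grid = vol@grid, data = arr)
}

#' Mask a scalar volume
#'
#' Sets values outside the mask to zero; values inside are unchanged. The
#' operation is idempotent and linear.
#'
#' @param vol a [ScalarVolume-class].
#' @param mask a [BinaryMask-class] on the same grid.
#' @return A [ScalarVolume-class].
#' @export
applyMask <- function(vol, mask) {
  checkSameGrid(vol@grid, mask@grid, "volume and mask")
  new("ScalarVolume", grid = vol@grid, data = vol@data * mask@data)
}
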