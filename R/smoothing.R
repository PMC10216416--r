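# Separable Gaussian smoothing of 3D arrays, used for the synthetic texture
# fields and for the gradient-based surface-area estimator. Zero padding at
# the borders.

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

conv1_along_dim <- function(a, kernel, dim_index) {
  if (length(kernel) == 1L) return(a * kernel)
  d <- dim(a)
  perm <- c(dim_index, setdiff(1:3, dim_index))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[dim_index])
  half <- (length(kernel) - 1L) / 2L
  pad <- matrix(0, nrow = half, ncol = ncol(m))
  mp <- rbind(pad, m, pad)
  f <- stats::filter(mp, kernel, method = "convolution", sides = 2)
  f <- f[(half + 1L):(half + d[dim_index]), , drop = FALSE]
  out <- array(as.numeric(f), dim = d[perm])
  aperm(out, order(perm))
}

#' Smooth a 3D array with an anisotropic Gaussian
#'
#' Separable convolution with per-axis standard deviations given in voxels.
#' Borders are zero-padded.
#'
#' @param a 3D numeric array.
#' @param sigma_vox numeric length 1 or 3; Gaussian SD per axis, in voxels.
#' @return smoothed array, same shape.
#' @keywords internal
gaussian_smooth_3d <- function(a, sigma_vox) {
  sigma_vox <- rep(as.numeric(sigma_vox), length.out = 3)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) a <- conv1_along_dim(a, gaussian_kernel_1d(sigma_vox[ax]), ax)
  }
  a
}
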