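# Separable 1-D convolution along array axes with symmetric (mirror) boundary
# handling. This is the numerical core shared by the Gaussian texture field of
# the phantom generator, the Laplacian-of-Gaussian filter and the undecimated
# wavelet transform.

# Map arbitrary integer indices onto 1..n by repeated edge-repeating mirror
# reflection (…3 2 1 | 1 2 3 … n | n n-1…), period 2n. Handles kernels wider
# than the axis.
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Convolve one axis of a 3-D array with a 1-D kernel. `center` is the kernel
# tap aligned with the output voxel (1-based); default centres odd kernels and
# uses the left-of-centre tap for even ones.
conv_axis <- function(arr, kernel, axis, center = (length(kernel) + 1L) %/% 2L) {
  d <- dim(arr)
  n <- d[axis]
  out <- array(0, d)
  for (k in seq_along(kernel)) {
    if (kernel[k] == 0) next
    src <- mirror_index(seq_len(n) + (k - center), n)
    shifted <- switch(axis,
      arr[src, , , drop = FALSE],
      arr[, src, , drop = FALSE],
      arr[, , src, drop = FALSE]
    )
    out <- out + kernel[k] * shifted
  }
  out
}

# Apply per-axis kernels in sequence (separable convolution). `kernels` is a
# list of length 3; NULL entries skip the axis.
conv_separable <- function(arr, kernels, centers = NULL) {
  for (a in 1:3) {
    if (is.null(kernels[[a]])) next
    ctr <- if (is.null(centers)) (length(kernels[[a]]) + 1L) %/% 2L else centers[[a]]
    arr <- conv_axis(arr, kernels[[a]], a, center = ctr)
  }
  arr
}

# Sampled Gaussian kernel (sd in voxels), truncated at `trunc` sd, sum 1.
gaussian_kernel <- function(sd_vox, trunc = 4) {
  if (sd_vox <= 0) return(1)
  r <- max(1L, ceiling(trunc * sd_vox))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sd_vox^2))
  g / sum(g)
}

# Sampled second derivative of a Gaussian (sd in voxels), sharing the sampled
# Gaussian's normalizer and projected to exact zero sum so that constants map
# to zero.
gaussian_d2_kernel <- function(sd_vox, trunc = 4) {
  r <- max(1L, ceiling(trunc * sd_vox))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sd_vox^2))
  z <- sum(g)
  k <- (x^2 / sd_vox^2 - 1) / sd_vox^2 * g / z
  k - mean(k)
}

# Smooth a 3-D array with an isotropic-in-mm Gaussian.
gaussian_smooth <- function(arr, sigma_mm, spacing) {
  kernels <- lapply(1:3, function(a) gaussian_kernel(sigma_mm / spacing[a]))
  conv_separable(arr, kernels)
}
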