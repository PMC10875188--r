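#' Composite projection of the opening fraction of a stack
#'
#' Sums (means) the first `fraction` of frames to boost the signal-to-noise
#' ratio of persistent foci, and takes the per-pixel maximum over the same
#' window so that fluorophores that bleach within the first frames still
#' appear. Both projections are min-max normalized to `[0, 1]`, combined
#' with equal weight, and renormalized to `[0, 1]`. A constant stack
#' (degenerate normalization) returns an all-zero image.
#'
#' @param stack An [image_stack()].
#' @param fraction Fraction of initial frames to project (default 0.2).
#' @return Matrix in `[0, 1]`.
#' @export
composite_projection <- function(stack, fraction = 0.2) {
  stopifnot(inherits(stack, "image_stack"), fraction > 0, fraction <= 1)
  nt <- n_frames(stack)
  m <- max(1L, ceiling(fraction * nt))
  sub <- stack$frames[, , seq_len(m), drop = FALSE]
  avg <- rowMeans(sub, dims = 2L)
  mx <- sub[, , 1L]
  if (m > 1L) for (i in 2:m) mx <- pmax(mx, sub[, , i])
  minmax_norm(0.5 * minmax_norm(avg) + 0.5 * minmax_norm(mx))
}

#' High-pass filter an image by Gaussian background subtraction
#'
#' Convolves the image with a large normalized Gaussian kernel (a low-pass
#' estimate of the smooth background) and subtracts the result from the
#' original, removing autofluorescence and illumination gradients while
#' leaving diffraction-limited foci essentially untouched. Boundaries are
#' handled by reflective padding.
#'
#' @param image Numeric matrix.
#' @param kernel_size Kernel size in pixels (odd-adjusted internally).
#' @param sigma Gaussian standard deviation in pixels.
#' @return Matrix of the same size (may contain negatives).
#' @export
highpass <- function(image, kernel_size = 128L, sigma = 32) {
  stopifnot(is.matrix(image), sigma > 0)
  k <- gauss_kernel1d(sigma, kernel_size)
  image - conv_sep2d(image, k)
}

#' Wavelet-style spot enhancement by matched-kernel correlation
#'
#' Correlates every pixel with a zero-mean, unit-norm spot-matched kernel
#' (a difference of Gaussians with `sigma2 = 2 * sigma1` by default) and
#' clips negative responses to zero, so the output is zero everywhere
#' except fluorescent foci where the overlap integral is high.
#'
#' @param image Numeric matrix.
#' @param sigma1 Centre Gaussian standard deviation, matched to the point
#'   spread function (default 1.3 px).
#' @param sigma2 Surround Gaussian standard deviation (default `2 * sigma1`).
#' @return Non-negative matrix of the same size.
#' @export
wavelet_enhance <- function(image, sigma1 = 1.3, sigma2 = 2 * sigma1) {
  stopifnot(is.matrix(image), sigma1 > 0, sigma2 > sigma1)
  size <- 2L * ceiling(3 * sigma2) + 1L
  k1 <- gauss_kernel1d(sigma1, size)
  k2 <- gauss_kernel1d(sigma2, size)
  # zero-mean by construction (both separable kernels integrate to 1);
  # normalize by the Frobenius norm of the 2-D DoG kernel
  K <- outer(k1, k1) - outer(k2, k2)
  nrm <- sqrt(sum(K^2))
  out <- (conv_sep2d(image, k1) - conv_sep2d(image, k2)) / nrm
  pmax(out, 0)
}
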