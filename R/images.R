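#' Construct a multi-frame image stack
#'
#' Frames are stored as a `height x width x n_frames` array of
#' non-negative counts (EMCCD-like). The channel label follows the
#' excitation-wavelength naming convention (e.g. `"640"`, `"561"`,
#' `"488"`).
#'
#' @param frames 3-D array (`h x w x t`) or a matrix (single frame).
#' @param pixel_size Pixel size in micrometres.
#' @param frame_duration Frame duration in seconds.
#' @param channel Excitation wavelength tag.
#' @return An `"image_stack"` object.
#' @export
image_stack <- function(frames, pixel_size = 0.1, frame_duration = 0.1,
                        channel = "640") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, all(dim(frames) >= 1L),
            all(is.finite(frames)))
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_duration = frame_duration, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d x %d px, %d frames, channel %s, %.3g um/px, %.3g s/frame\n",
              d[1], d[2], d[3], x$channel, x$pixel_size, x$frame_duration))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

#' Write an image stack as multi-page 16-bit TIFF
#'
#' Counts are stored as 16-bit unsigned integers; values are clamped to
#' `[0, 65535]`.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  fr <- lapply(seq_len(n_frames(stack)), function(i) {
    clamp(stack$frames[, , i], 0, 65535) / 65535
  })
  tiff::writeTIFF(fr, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file.
#' @inheritParams image_stack
#' @return An [image_stack()] with counts on the 16-bit scale.
#' @export
read_stack_tiff <- function(path, pixel_size = 0.1, frame_duration = 0.1,
                            channel = "640") {
  fr <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(fr)) fr <- list(fr)
  arr <- array(0, dim = c(dim(fr[[1]])[1:2], length(fr)))
  for (i in seq_along(fr)) {
    f <- fr[[i]]
    if (length(dim(f)) == 3L) f <- f[, , 1]
    arr[, , i] <- f * 65535
  }
  image_stack(arr, pixel_size, frame_duration, channel)
}

# ---- separable convolution with reflective padding -------------------------

gauss_kernel1d <- function(sigma, size = NULL) {
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  if (size %% 2L == 0L) size <- size + 1L  # odd-adjusted
  r <- (size - 1L) / 2L
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Band matrix applying 1-D kernel k along an axis of length n with mirror
# padding; convolution is then two dense matrix products (fast via BLAS).
conv_band_matrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  idx <- seq_len(n + 2L * r) - r        # padded positions mapped to 1..n
  while (any(idx < 1L | idx > n)) {     # fold until inside (kernels wider
    idx <- ifelse(idx < 1L, 2L - idx, idx)    # than the image reflect again)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
  }
  B <- matrix(0, n, n)
  for (j in seq_along(k)) {
    rows <- seq_len(n)
    cols <- idx[rows + (j - 1L)]
    B[cbind(rows, cols)] <- B[cbind(rows, cols)] + k[j]
  }
  B
}

# 2-D correlation of an image with a separable kernel kx (rows) x ky (cols),
# reflective boundary.
conv_sep2d <- function(img, krow, kcol = krow) {
  Br <- conv_band_matrix(nrow(img), krow)
  Bc <- conv_band_matrix(ncol(img), kcol)
  Br %*% img %*% t(Bc)
}

minmax_norm <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(img * 0)  # constant image -> zeros
  (img - rng[1]) / (rng[2] - rng[1])
}
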