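# Shared fixtures: small rendered images and memoised trained networks.
# Everything is generated in code at test time; the trained models are
# shared across test files through a session-local cache because training,
# not inference, is the expensive part.

.fixture_cache <- new.env(parent = emptyenv())

# Render a frame with Gaussian spots at given positions on a flat
# background with optional Gaussian noise.
render_frame <- function(h, w, x, y, amplitude, sigma = 1.3, noise_sd = 0,
                         baseline = 0) {
  img <- matrix(baseline, h, w)
  for (i in seq_along(x)) {
    rows <- max(1, round(y[i]) - 6):min(h, round(y[i]) + 6)
    cols <- max(1, round(x[i]) - 6):min(w, round(x[i]) + 6)
    ry <- exp(-(rows - y[i])^2 / (2 * sigma^2))
    cx <- exp(-(cols - x[i])^2 / (2 * sigma^2))
    img[rows, cols] <- img[rows, cols] + amplitude[min(i, length(amplitude))] * (ry %o% cx)
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
  img
}

# Independent brute-force implementation of the average step
# signal-to-noise ratio: literal evaluation, plateau by plateau.
asnr_bruteforce <- function(x, bounds) {
  seg <- c(1L, as.integer(bounds), length(x) + 1L)
  k <- length(seg) - 1L
  means <- sds <- numeric(k)
  for (i in seq_len(k)) {
    v <- x[seg[i]:(seg[i + 1L] - 1L)]
    means[i] <- sum(v) / length(v)
    sds[i] <- sqrt(sum((v - means[i])^2) / (length(v) - 1L))
  }
  total <- 0
  for (i in seq_len(k - 1L)) {
    total <- total + 2 * abs(means[i] - means[i + 1L]) / (sds[i] + sds[i + 1L])
  }
  total / (k - 1L)
}

# Independent brute-force MSD (double loop over the definition).
msd_bruteforce <- function(track, frame_duration, pixel_size) {
  frames <- track$frame
  out <- data.frame()
  for (dn in 1:(max(frames) - min(frames))) {
    acc <- 0; cnt <- 0L
    for (i in seq_len(nrow(track))) {
      j <- which(frames == frames[i] + dn)
      if (length(j) != 1L) next
      # skip pairs spanning a gap
      if (!all((frames[i]:(frames[i] + dn)) %in% frames)) next
      acc <- acc + (track$x[j] - track$x[i])^2 + (track$y[j] - track$y[i])^2
      cnt <- cnt + 1L
    }
    if (cnt > 0L) {
      out <- rbind(out, data.frame(tau = dn * frame_duration,
                                   msd = acc / cnt * pixel_size^2,
                                   n_pairs = cnt))
    }
  }
  out
}

# Memoised fast-preset step-count model shared by the acceptance tests.
trained_crnn <- function() {
  if (is.null(.fixture_cache$crnn)) {
    .fixture_cache$crnn <- train_crnn(
      build_model(seed = 101), n_per_class = 5000L,
      cfg = train_config(epochs = 4L, learning_rate = 1e-3, batch_size = 512L),
      val_per_class = 200L, seed = 7L)
  }
  .fixture_cache$crnn
}

trained_posnet <- function() {
  if (is.null(.fixture_cache$posnet)) {
    .fixture_cache$posnet <- train_position_model(
      build_position_model(seed = 201), n_traces = 8000L, epochs = 4L,
      batch_size = 128L, lr = 1e-3, seed = 11L)
  }
  .fixture_cache$posnet
}
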