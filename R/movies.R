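#' Specify a synthetic single-molecule movie
#'
#' Complexes are rendered as 2-D Gaussian functions (`psf_sigma`, default
#' 1.3 px) whose amplitude in each frame is the sum of the intensities of
#' the complex's surviving fluorophores; fluorophores bleach stochastically
#' with constant per-frame probability. Each frame adds Gaussian dark
#' current, a smooth non-uniform autofluorescence offset (low-order 2-D
#' polynomial surface), and gamma-distributed shot noise on the signal to
#' account for EMCCD gain.
#'
#' @param n_complexes Number of complexes in the field.
#' @param n_frames,height,width Stack dimensions.
#' @param stoichiometry `list(type = "binomial", size =, prob =)` or
#'   `list(type = "fixed", n =)` giving the per-complex label count.
#' @param psf_sigma Point-spread-function standard deviation in pixels.
#' @param fluor_amplitude Peak counts contributed by one fluorophore.
#' @param dark_noise_sigma Gaussian dark-current standard deviation
#'   (counts).
#' @param baseline Constant camera offset (counts).
#' @param autofluorescence Peak-to-peak amplitude of the smooth background
#'   field (counts); 0 disables it.
#' @param gain_shape Gamma shape parameter for the signal shot noise
#'   (relative noise `1/sqrt(gain_shape)`); `Inf` disables shot noise.
#' @param bleach_prob Per-frame bleaching probability (default: 40.5-frame
#'   half-life).
#' @param step_model Step-height model for the fluorophores (see
#'   [trace_sim_spec()]).
#' @param min_separation Minimum distance between complex centres (px);
#'   the default keeps a neighbouring complex outside another's 11 x 11
#'   fitting patch and out of the background annulus core.
#' @param margin Border kept free of complexes (px).
#' @param pixel_size,frame_duration Stack metadata.
#' @return A `"movie_sim_spec"` object.
#' @export
movie_sim_spec <- function(n_complexes,
                           n_frames = 300L, height = 256L, width = 256L,
                           stoichiometry = list(type = "binomial", size = 2L, prob = 0.5),
                           psf_sigma = 1.3,
                           fluor_amplitude = 160,
                           dark_noise_sigma = 10,
                           baseline = 100,
                           autofluorescence = 30,
                           gain_shape = 50,
                           bleach_prob = 1 - 2^(-1 / 40.5),
                           step_model = "constant_pm20",
                           min_separation = 12,
                           margin = 10,
                           pixel_size = 0.1,
                           frame_duration = 0.1) {
  stopifnot(psf_sigma > 0, n_frames >= 1, height >= 16, width >= 16,
            min_separation > 0, dark_noise_sigma >= 0)
  structure(as.list(environment()), class = "movie_sim_spec")
}

# Poisson-disc-like placement by rejection; errors when the field cannot
# accommodate the requested number of complexes at the separation.
place_positions <- function(n, height, width, min_sep, margin) {
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    x <- stats::runif(1, 1 + margin, width - margin)
    y <- stats::runif(1, 1 + margin, height - margin)
    if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
      xs <- c(xs, x); ys <- c(ys, y); tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > 2000L) stop("field too small for n_complexes at the requested separation")
    }
  }
  data.frame(x = xs, y = ys)
}

# Smooth low-order polynomial background surface scaled to [0, amplitude].
autofluor_field <- function(height, width, amplitude) {
  if (amplitude <= 0) return(matrix(0, height, width))
  u <- (seq_len(height) - 1) / (height - 1) - 0.5
  v <- (seq_len(width) - 1) / (width - 1) - 0.5
  cf <- stats::rnorm(6)
  f <- outer(u, v, function(a, b)
    cf[1] * a + cf[2] * b + cf[3] * a * b + cf[4] * a^2 + cf[5] * b^2 + cf[6] * a^2 * b)
  amplitude * minmax_norm(f)
}

draw_label_counts <- function(n, stoich) {
  switch(stoich$type,
    binomial = stats::rbinom(n, stoich$size, stoich$prob),
    fixed = rep.int(as.integer(stoich$n), n),
    stop("unknown stoichiometry type"))
}

# Gaussian patch (point-sampled at pixel centres) around (x0, y0);
# returns row/col index ranges and the separable profile vectors.
psf_patch <- function(x0, y0, sigma, height, width, r = NULL) {
  if (is.null(r)) r <- ceiling(4 * sigma)
  rows <- max(1L, round(y0) - r):min(height, round(y0) + r)
  cols <- max(1L, round(x0) - r):min(width, round(x0) + r)
  list(rows = rows, cols = cols,
       ry = exp(-(rows - y0)^2 / (2 * sigma^2)),
       cx = exp(-(cols - x0)^2 / (2 * sigma^2)))
}

#' Simulate a single-molecule TIRF movie with ground truth
#'
#' @param spec A [movie_sim_spec()].
#' @param seed Integer seed.
#' @return List with `stack` (an [image_stack()]) and `truth`, a data frame
#'   with one row per complex: `complex_id`, `x`, `y` (1-based pixel-centre
#'   coordinates), `n_labels`, and `bleach_frames` (semicolon-separated,
#'   1-based first frame at the lowered level).
#' @export
simulate_movie <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "movie_sim_spec"))
  set.seed(seed)
  h <- spec$height; w <- spec$width; nt <- spec$n_frames
  pos <- place_positions(spec$n_complexes, h, w, spec$min_separation, spec$margin)
  labels <- draw_label_counts(spec$n_complexes, spec$stoichiometry)

  # per-complex fluorophore heights and bleach times
  heights <- lapply(labels, function(k)
    spec$fluor_amplitude * draw_step_heights(k, spec$step_model))
  emitted <- lapply(labels, function(k)
    if (k > 0L) stats::rgeom(k, spec$bleach_prob) else integer(0))

  # amplitude of each complex in each frame
  amp <- matrix(0, nrow = spec$n_complexes, ncol = nt)
  for (i in seq_len(spec$n_complexes)) {
    if (labels[i] == 0L) next
    for (j in seq_along(heights[[i]])) {
      ne <- emitted[[i]][j]
      if (ne >= 1L) amp[i, seq_len(min(ne, nt))] <- amp[i, seq_len(min(ne, nt))] + heights[[i]][j]
    }
  }

  patches <- lapply(seq_len(spec$n_complexes), function(i)
    psf_patch(pos$x[i], pos$y[i], spec$psf_sigma, h, w))
  autofl <- autofluor_field(h, w, spec$autofluorescence)

  frames <- array(0, dim = c(h, w, nt))
  for (t in seq_len(nt)) {
    sig <- matrix(0, h, w)
    for (i in seq_len(spec$n_complexes)) {
      a <- amp[i, t]
      if (a <= 0) next
      p <- patches[[i]]
      sig[p$rows, p$cols] <- sig[p$rows, p$cols] + a * (p$ry %o% p$cx)
    }
    if (is.finite(spec$gain_shape)) {
      nz <- which(sig > 1e-3)
      if (length(nz)) {
        sig[nz] <- stats::rgamma(length(nz), shape = spec$gain_shape,
                                 scale = sig[nz] / spec$gain_shape)
      }
    }
    frames[, , t] <- spec$baseline + autofl + sig +
      if (spec$dark_noise_sigma > 0) stats::rnorm(h * w, 0, spec$dark_noise_sigma) else 0
  }

  truth <- data.frame(
    complex_id = seq_len(spec$n_complexes),
    x = pos$x, y = pos$y, n_labels = labels,
    bleach_frames = vapply(emitted, function(e)
      paste(sort(pmin(e, spec$n_frames) + 1L)[e < spec$n_frames], collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)

  list(stack = image_stack(frames, spec$pixel_size, spec$frame_duration),
       truth = truth, amplitude = amp, seed = seed)
}

#' Specify a Brownian-diffusion movie
#'
#' @param species Data frame or list of lists with columns/fields `D`
#'   (diffusion coefficient, um^2/s) and `count` (number of emitters).
#' @param n_frames,height,width,pixel_size,frame_duration As in
#'   [movie_sim_spec()]; `frame_duration` defaults to 0.1 s (100 ms time
#'   bins).
#' @param fluor_amplitude,dark_noise_sigma,baseline,autofluorescence,gain_shape
#'   Emitter brightness and noise, as in [movie_sim_spec()].
#' @param psf_sigma PSF standard deviation (px).
#' @param bleach_prob Per-frame bleaching probability (0 disables).
#' @return A `"diffusion_sim_spec"` object.
#' @export
diffusion_sim_spec <- function(species,
                               n_frames = 300L, height = 128L, width = 128L,
                               pixel_size = 0.1, frame_duration = 0.1,
                               psf_sigma = 1.3,
                               fluor_amplitude = 300,
                               dark_noise_sigma = 10,
                               baseline = 100,
                               autofluorescence = 0,
                               gain_shape = 50,
                               bleach_prob = 0) {
  if (is.list(species) && !is.data.frame(species))
    species <- do.call(rbind, lapply(species, as.data.frame))
  stopifnot(is.data.frame(species), all(c("D", "count") %in% names(species)),
            all(species$D >= 0), pixel_size > 0)
  structure(as.list(environment()), class = "diffusion_sim_spec")
}

#' Simulate ground-truth Brownian tracks (no rendering)
#'
#' Each emitter performs 2-D Brownian motion with per-frame, per-axis
#' displacements of variance `2 * D * frame_duration` (converted to
#' pixels); paths reflect at the field boundary.
#'
#' @param spec A [diffusion_sim_spec()].
#' @param seed Integer seed.
#' @return Data frame `track_id`, `frame`, `x`, `y` (px), `D_true`
#'   (um^2/s).
#' @export
simulate_diffusion_tracks <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "diffusion_sim_spec"))
  set.seed(seed)
  h <- spec$height; w <- spec$width; nt <- spec$n_frames
  out <- list(); id <- 0L
  for (si in seq_len(nrow(spec$species))) {
    D <- spec$species$D[si]
    step_sd <- sqrt(2 * D * spec$frame_duration) / spec$pixel_size
    if (step_sd * 6 > min(h, w)) stop("displacement scale exceeds the field size")
    for (e in seq_len(spec$species$count[si])) {
      id <- id + 1L
      x <- numeric(nt); y <- numeric(nt)
      x[1] <- stats::runif(1, 6, w - 5)
      y[1] <- stats::runif(1, 6, h - 5)
      if (nt > 1L) {
        dx <- stats::rnorm(nt - 1L, 0, step_sd)
        dy <- stats::rnorm(nt - 1L, 0, step_sd)
        x[-1] <- x[1] + cumsum(dx)
        y[-1] <- y[1] + cumsum(dy)
        x <- reflect_coord(x, 1.5, w - 0.5)
        y <- reflect_coord(y, 1.5, h - 0.5)
      }
      out[[id]] <- data.frame(track_id = id, frame = seq_len(nt),
                              x = x, y = y, D_true = D)
    }
  }
  do.call(rbind, out)
}

reflect_coord <- function(v, lo, hi) {
  span <- hi - lo
  u <- (v - lo) %% (2 * span)
  lo + ifelse(u > span, 2 * span - u, u)
}

#' Simulate a Brownian-diffusion movie with ground-truth tracks
#'
#' Renders the tracks from [simulate_diffusion_tracks()] with the same
#' EMCCD-like noise model as [simulate_movie()].
#'
#' @inheritParams simulate_diffusion_tracks
#' @return List with `stack` (an [image_stack()]) and `truth` (the track
#'   table).
#' @export
simulate_diffusion_movie <- function(spec, seed = 1L) {
  tracks <- simulate_diffusion_tracks(spec, seed)
  h <- spec$height; w <- spec$width; nt <- spec$n_frames
  n_em <- max(tracks$track_id)
  alive_until <- if (spec$bleach_prob > 0)
    stats::rgeom(n_em, spec$bleach_prob) else rep(nt, n_em)
  autofl <- autofluor_field(h, w, spec$autofluorescence)
  frames <- array(0, dim = c(h, w, nt))
  xs <- split(tracks$x, tracks$track_id)
  ys <- split(tracks$y, tracks$track_id)
  for (t in seq_len(nt)) {
    sig <- matrix(0, h, w)
    for (i in seq_len(n_em)) {
      if (t > alive_until[i]) next
      p <- psf_patch(xs[[i]][t], ys[[i]][t], spec$psf_sigma, h, w)
      sig[p$rows, p$cols] <- sig[p$rows, p$cols] +
        spec$fluor_amplitude * (p$ry %o% p$cx)
    }
    if (is.finite(spec$gain_shape)) {
      nz <- which(sig > 1e-3)
      if (length(nz)) sig[nz] <- stats::rgamma(length(nz), shape = spec$gain_shape,
                                               scale = sig[nz] / spec$gain_shape)
    }
    frames[, , t] <- spec$baseline + autofl + sig +
      if (spec$dark_noise_sigma > 0) stats::rnorm(h * w, 0, spec$dark_noise_sigma) else 0
  }
  list(stack = image_stack(frames, spec$pixel_size, spec$frame_duration),
       truth = tracks, alive_until = pmin(alive_until, nt), seed = seed)
}
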