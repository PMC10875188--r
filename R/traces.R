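#' Specify a synthetic photobleaching trace
#'
#' Describes the generative model for one single-molecule fluorescence
#' intensity time course: a set of fluorophores that each bleach
#' irreversibly with a constant per-frame probability (geometric lifetime),
#' with per-fluorophore step heights drawn from a dye-like
#' (`"constant_pm20"`, unit height +/- 20%) or protein-fluorophore-like
#' (`"cos2"`, squared-cosine dipole orientation) distribution, and i.i.d.
#' Gaussian noise scaled so that the realized average step signal-to-noise
#' ratio (see [compute_asnr()]) matches `target_asnr`.
#'
#' A bleaching half-life of `h` frames corresponds to
#' `bleach_prob = 1 - 2^(-1/h)`; the default uses the 40.5-frame half-life
#' typical of the movie simulations in this package.
#'
#' @param n_fluorophores Integer >= 0, number of emitters in the focus.
#' @param n_frames Trace length in frames (>= 2).
#' @param bleach_prob Per-frame bleaching probability in (0, 1].
#' @param step_model `"constant_pm20"` or `"cos2"`.
#' @param target_asnr Positive scalar, a length-2 range from which one
#'   value is drawn uniformly per trace, or a mixture
#'   `list(ranges = list(c(lo, hi), ...), weights = c(...))` of uniform
#'   segments.
#' @param blinking Optional list `list(p_off =, p_on =)` enabling a
#'   two-state on/off Markov chain per fluorophore (default: no blinking).
#' @param leave_unbleached If `TRUE`, at least one fluorophore survives the
#'   whole recording, producing a trace whose stoichiometry is undecided
#'   (the "undefined" class).
#' @param frame_duration Seconds per frame (metadata only).
#' @param cos2_floor Minimum relative amplitude under the `"cos2"` model;
#'   in-plane dipoles still experience roughly 10% of the peak field.
#' @return An object of class `"trace_sim_spec"`.
#' @export
trace_sim_spec <- function(n_fluorophores,
                           n_frames = 300L,
                           bleach_prob = 1 - 2^(-1 / 40.5),
                           step_model = c("constant_pm20", "cos2"),
                           target_asnr = 6,
                           blinking = NULL,
                           leave_unbleached = FALSE,
                           frame_duration = 0.1,
                           cos2_floor = 0.10) {
  step_model <- match.arg(step_model)
  if (!is.numeric(n_fluorophores) || length(n_fluorophores) != 1L ||
      n_fluorophores < 0 || n_fluorophores != round(n_fluorophores))
    stop("n_fluorophores must be a non-negative integer")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (!(bleach_prob > 0 && bleach_prob <= 1)) stop("bleach_prob must be in (0, 1]")
  if (!valid_target_asnr(target_asnr))
    stop("target_asnr must be positive (scalar, length-2 range, or a mixture list)")
  if (!is.null(blinking)) {
    stopifnot(is.list(blinking), all(c("p_off", "p_on") %in% names(blinking)))
  }
  structure(list(
    n_fluorophores = as.integer(n_fluorophores),
    n_frames = as.integer(n_frames),
    bleach_prob = bleach_prob,
    step_model = step_model,
    target_asnr = target_asnr,
    blinking = blinking,
    leave_unbleached = isTRUE(leave_unbleached),
    frame_duration = frame_duration,
    cos2_floor = cos2_floor
  ), class = "trace_sim_spec")
}

# A length-2 target_asnr is a sampling range, drawn uniformly per trace so
# every part of the signal-to-noise range is equally represented in
# training data. A list(ranges = list(c(lo, hi), ...), weights = c(...))
# samples a mixture of uniform segments, which lets a training set stay
# dense in the hard low-SNR regime while still covering the bright tail.
sample_target_asnr <- function(target) {
  if (is.list(target)) {
    stopifnot(all(c("ranges", "weights") %in% names(target)))
    i <- sample.int(length(target$ranges), 1L, prob = target$weights)
    r <- target$ranges[[i]]
    return(stats::runif(1, r[1], r[2]))
  }
  if (length(target) == 2L) stats::runif(1, target[1], target[2]) else target
}

valid_target_asnr <- function(target) {
  if (is.list(target)) {
    all(c("ranges", "weights") %in% names(target)) &&
      all(unlist(target$ranges) > 0) && all(target$weights >= 0)
  } else {
    length(target) %in% 1:2 && all(target > 0)
  }
}

draw_step_heights <- function(n, step_model, cos2_floor = 0.10) {
  if (n == 0L) return(numeric(0))
  switch(step_model,
    constant_pm20 = stats::runif(n, 0.8, 1.2),
    cos2 = {
      theta <- stats::runif(n, 0, pi / 2)
      pmax(cos(theta)^2, cos2_floor)
    }
  )
}

#' Simulate one photobleaching trace with ground truth
#'
#' Generates an idealized piecewise-constant trace by stochastic
#' photobleaching (each surviving fluorophore independently bleaches each
#' frame with `spec$bleach_prob`; bleaching before the first frame is
#' possible, in which case the fluorophore contributes to no plateau but its
#' step is still counted at frame 1), then superimposes i.i.d. Gaussian
#' noise rescaled once so the realized aSNR matches the target.
#'
#' Ground truth records, per bleached fluorophore, the first frame of the
#' lowered plateau (`step_frames`, 1-based, non-decreasing; simultaneous
#' bleaching events produce duplicated frames and are counted separately),
#' the per-fluorophore step heights, and the ideal (noise-free) trace.
#'
#' @param spec A [trace_sim_spec()].
#' @param seed Integer seed.
#' @param restrict_plateaus If `TRUE`, apply the training-data plateau
#'   length restriction (see [apply_plateau_restriction()]) so that steps
#'   unresolvable at the target aSNR are pushed apart. Use only for
#'   training data; test data keeps fully stochastic bleaching.
#' @return A `"trace_record"` list with elements `intensity`,
#'   `frame_duration`, `asnr` (realized), and `truth` (list with
#'   `step_count`, `step_frames`, `step_heights`, `plateau_means`,
#'   `n_survivors`, `ideal`).
#' @export
simulate_trace <- function(spec, seed = NULL, restrict_plateaus = FALSE) {
  stopifnot(inherits(spec, "trace_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_fluorophores
  nf <- spec$n_frames

  target <- sample_target_asnr(spec$target_asnr)

  heights <- draw_step_heights(n, spec$step_model, spec$cos2_floor)
  # frames emitted before bleaching; geometric with mean 1/p - 1
  emitted <- if (n > 0L) stats::rgeom(n, spec$bleach_prob) else integer(0)
  if (spec$leave_unbleached && n > 0L) emitted[n] <- nf  # forced survivor

  bleached <- emitted < nf
  step_frames <- sort(emitted[bleached] + 1L)  # first frame of lowered plateau

  if (restrict_plateaus && length(step_frames) > 1L) {
    step_frames <- apply_plateau_restriction(step_frames, target,
                                             n_frames = nf)
  }
  # reassign (possibly shifted) step frames to the bleached fluorophores
  ord <- order(emitted[bleached])
  emitted_adj <- emitted
  emitted_adj[which(bleached)[ord]] <- step_frames - 1L

  ideal <- numeric(nf)
  frames <- seq_len(nf)
  on_mask <- matrix(TRUE, nrow = nf, ncol = max(n, 1L))
  if (n > 0L) {
    for (i in seq_len(n)) {
      alive <- frames <= emitted_adj[i]
      if (!is.null(spec$blinking) && any(alive)) {
        alive <- alive & simulate_blink_mask(nf, spec$blinking)
      }
      on_mask[, i] <- alive
      ideal <- ideal + heights[i] * alive
    }
  }

  # plateau structure of the ideal trace (ignoring blinking) for noise scaling
  sf <- sort(emitted_adj[bleached] + 1L)
  bounds <- unique(sf[sf >= 2L & sf <= nf])
  seg <- c(1L, bounds, nf + 1L)
  plat_means <- vapply(seq_len(length(seg) - 1L), function(i) {
    mean(ideal[seg[i]:(seg[i + 1L] - 1L)])
  }, numeric(1))
  u <- abs(diff(plat_means))
  u_ref <- if (length(u) > 0 && any(u > 0)) mean(u[u > 0]) else mean(c(heights, 1))

  sigma0 <- u_ref / target
  eps <- stats::rnorm(nf, 0, sigma0)
  realized <- asnr_from_bounds(ideal + eps, bounds)
  if (is.finite(realized) && realized > 0) {
    eps <- eps * (realized / target)
  }
  intensity <- ideal + eps
  asnr <- asnr_from_bounds(intensity, bounds)

  structure(list(
    intensity = intensity,
    frame_duration = spec$frame_duration,
    asnr = asnr,
    target_asnr = target,
    noise_sd = stats::sd(eps),
    seed = seed,
    truth = list(
      step_count = sum(bleached),
      step_frames = sort(emitted_adj[bleached] + 1L),
      step_heights = heights[bleached][order(emitted_adj[bleached])],
      plateau_means = plat_means,
      n_survivors = sum(!bleached),
      ideal = ideal
    )
  ), class = "trace_record")
}

simulate_blink_mask <- function(nf, blinking) {
  # two-state Markov chain, starts in the emitting state
  p_off <- blinking$p_off
  p_on <- blinking$p_on
  state <- logical(nf)
  s <- TRUE
  u <- stats::runif(nf)
  for (t in seq_len(nf)) {
    state[t] <- s
    s <- if (s) u[t] >= p_off else u[t] < p_on
  }
  state
}

# aSNR over adjacent plateau pairs where both plateaus have >= 2 frames;
# lenient internal version used for noise calibration.
asnr_from_bounds <- function(x, step_frames) {
  nf <- length(x)
  seg <- c(1L, step_frames, nf + 1L)
  len <- diff(seg)
  k <- length(len)
  if (k < 2L) return(NA_real_)
  m <- s <- numeric(k)
  for (i in seq_len(k)) {
    idx <- seg[i]:(seg[i + 1L] - 1L)
    m[i] <- mean(x[idx]); s[i] <- stats::sd(x[idx])
  }
  ok <- which(len[-k] >= 2L & len[-1L] >= 2L)
  if (length(ok) == 0L) return(NA_real_)
  vals <- 2 * abs(m[ok + 1L] - m[ok]) / (s[ok] + s[ok + 1L])
  mean(vals)
}

#' Average step signal-to-noise ratio of a trace
#'
#' For `k` plateaus separated by `k - 1` steps, the aSNR is
#' `mean over i of 2 * |mean_i - mean_(i+1)| / (sd_i + sd_(i+1))`,
#' i.e. twice the plateau mean difference divided by the summed flanking
#' plateau standard deviations, averaged over steps.
#'
#' @param trace A `"trace_record"` or a numeric intensity vector.
#' @param plateau_bounds Increasing 1-based frame indices, each the first
#'   frame of a new plateau; `k - 1` bounds define `k` plateaus. Every
#'   plateau must contain at least 2 frames.
#' @return The aSNR. If both plateaus flanking every step have zero
#'   standard deviation the trace is noiseless and `Inf` is returned
#'   (infinite aSNR signalled distinctly).
#' @export
compute_asnr <- function(trace, plateau_bounds) {
  x <- if (inherits(trace, "trace_record")) trace$intensity else as.numeric(trace)
  nf <- length(x)
  b <- as.integer(plateau_bounds)
  if (is.unsorted(b, strictly = TRUE)) stop("plateau_bounds must be strictly increasing")
  if (length(b) < 1L) stop("aSNR undefined: trace has no steps (fewer than 2 plateaus)")
  if (any(b < 2L) || any(b > nf)) stop("plateau_bounds out of range")
  seg <- c(1L, b, nf + 1L)
  if (any(diff(seg) < 2L)) stop("every plateau must contain at least 2 frames")
  k <- length(seg) - 1L
  m <- s <- numeric(k)
  for (i in seq_len(k)) {
    idx <- seg[i]:(seg[i + 1L] - 1L)
    m[i] <- mean(x[idx]); s[i] <- stats::sd(x[idx])
  }
  denom <- s[-k] + s[-1L]
  u <- abs(diff(m))
  if (all(denom == 0)) return(Inf)
  mean(2 * u / denom)
}

#' Enforce resolvable plateau lengths in training traces
#'
#' At very low signal-to-noise ratios two nearby bleaching steps are
#' statistically unresolvable from a single larger step. For training data
#' only, the intermediate plateau is extended: a step following another
#' within the minimum separation is deferred until the plateau between them
#' is long enough to resolve at the given aSNR. The number of steps is
#' unchanged.
#'
#' The minimum separation is `ceiling(c / asnr^2)` frames, clamped to
#' `[1, 20]`; at aSNR >= 8 the restriction is inactive (1 frame, the
#' stochastic minimum). The constant `c` is configurable.
#'
#' @param step_frames Sorted step frames (1-based).
#' @param target_asnr The trace's target aSNR.
#' @param c Resolvability constant (default 25).
#' @param cap Bounds for the separation in frames.
#' @param n_frames Trace length; deferred steps are clamped to it.
#' @return Adjusted non-decreasing step frames, same length.
#' @export
apply_plateau_restriction <- function(step_frames, target_asnr, c = 25,
                                      cap = c(1L, 20L), n_frames = 300L) {
  if (length(step_frames) <= 1L) return(step_frames)
  min_sep <- as.integer(clamp(ceiling(c / target_asnr^2), cap[1], cap[2]))
  out <- as.integer(sort(step_frames))
  for (j in 2:length(out)) {
    if (out[j] < out[j - 1L] + min_sep) out[j] <- out[j - 1L] + min_sep
  }
  pmin(out, as.integer(n_frames))
}

#' Resample a trace to a fixed length by linear interpolation
#'
#' The step-count network has a fixed 300-neuron input layer, so any trace
#' entering the model is resampled to 300 points with a linear
#' interpolator; endpoints are preserved. Note that interpolation
#' introduces intermediate points between plateaus, which degrades accuracy
#' once interpolated runs approach the length of real plateaus.
#'
#' @param trace A `"trace_record"` or numeric vector of length >= 2.
#' @param target_len Output length (default 300).
#' @return Numeric vector of length `target_len` (or a `"trace_record"`
#'   with resampled intensity when given one).
#' @export
resample_trace <- function(trace, target_len = 300L) {
  is_rec <- inherits(trace, "trace_record")
  x <- if (is_rec) trace$intensity else as.numeric(trace)
  if (length(x) < 2L) stop("trace must have at least 2 frames")
  y <- stats::approx(seq_along(x), x, n = target_len)$y
  if (is_rec) {
    trace$intensity <- y
    trace
  } else y
}
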