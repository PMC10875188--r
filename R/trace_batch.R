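#' Class labels used by the step-count classifier
#'
#' Seven classes: 0 to 4 steps, `"5+"` (five or more), and `"undefined"`
#' (at least one fluorophore survives the recording, so the final plateau
#' stays above zero and the stoichiometry is undecided).
#' @export
step_class_labels <- function() c("0", "1", "2", "3", "4", "5+", "undefined")

#' Generate a class-balanced set of synthetic traces
#'
#' Draws `n_per_class` traces for each of the seven step-count classes.
#' For classes 0-4 and "5+" every fluorophore bleaches within the
#' recording (traces with accidental survivors are redrawn); "undefined"
#' traces keep one forced survivor. Class "5+" uses 5-8 fluorophores.
#'
#' @param n_per_class Traces per class.
#' @param seed Integer seed.
#' @param n_frames Trace length.
#' @param step_model `"constant_pm20"` (dye-like) or `"cos2"`
#'   (protein-fluorophore-like).
#' @param target_asnr Scalar or length-2 uniform sampling range.
#' @param bleach_prob Per-frame bleaching probability.
#' @param restrict_plateaus Apply the training-only plateau length
#'   restriction (see [apply_plateau_restriction()]).
#' @param step_positions `"geometric"` for stochastic constant-hazard
#'   bleaching, `"uniform"` for step times drawn uniformly over the trace
#'   (rectangular distribution, used to train the step-position network
#'   without temporal class imbalance).
#' @param blinking Optional blinking parameters, see [trace_sim_spec()].
#' @return List with `x` (matrix, traces in rows), `label` (integer step
#'   class, 0..5 for 0-4 and 5+, 6 for undefined), `class` (factor),
#'   `asnr`, and `step_frames` (list of 1-based step frames).
#' @export
simulate_trace_batch <- function(n_per_class, seed = 1L, n_frames = 300L,
                                 step_model = "constant_pm20",
                                 target_asnr = c(1, 10),
                                 bleach_prob = 1 - 2^(-1 / 40.5),
                                 restrict_plateaus = FALSE,
                                 step_positions = c("geometric", "uniform"),
                                 blinking = NULL) {
  step_positions <- match.arg(step_positions)
  labels <- step_class_labels()
  n_tot <- n_per_class * length(labels)
  x <- matrix(0, nrow = n_tot, ncol = n_frames)
  lab <- integer(n_tot)
  asnr <- numeric(n_tot)
  sf_list <- vector("list", n_tot)
  set.seed(seed)
  row <- 0L
  for (ci in seq_along(labels)) {
    cls <- labels[ci]
    for (j in seq_len(n_per_class)) {
      row <- row + 1L
      nfl <- switch(cls,
        "0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L,
        "5+" = sample(5:8, 1L),
        "undefined" = sample(1:5, 1L))
      spec <- trace_sim_spec(
        n_fluorophores = nfl, n_frames = n_frames,
        bleach_prob = bleach_prob, step_model = step_model,
        target_asnr = target_asnr, blinking = blinking,
        leave_unbleached = (cls == "undefined"))
      repeat {
        tr <- simulate_trace(spec, restrict_plateaus = restrict_plateaus)
        if (step_positions == "uniform" && nfl > 0L) {
          tr <- uniform_position_trace(spec, restrict_plateaus)
        }
        if (cls == "undefined" || tr$truth$n_survivors == 0L) break
      }
      x[row, ] <- tr$intensity
      lab[row] <- ci - 1L
      asnr[row] <- tr$asnr
      sf_list[[row]] <- tr$truth$step_frames
    }
  }
  ord <- sample.int(n_tot)
  list(x = x[ord, , drop = FALSE], label = lab[ord],
       class = factor(labels[lab[ord] + 1L], levels = labels),
       asnr = asnr[ord], step_frames = sf_list[ord])
}

# Trace whose step times are uniform over the frame range (training data
# for the step-position network), reusing the noise calibration of
# simulate_trace by overriding the bleach-time draw.
uniform_position_trace <- function(spec, restrict_plateaus = FALSE) {
  nf <- spec$n_frames
  n <- spec$n_fluorophores
  target <- sample_target_asnr(spec$target_asnr)
  heights <- draw_step_heights(n, spec$step_model, spec$cos2_floor)
  emitted <- sample.int(nf, n, replace = TRUE) - 1L  # 0 .. nf-1 frames emitted
  step_frames <- sort(emitted + 1L)
  if (restrict_plateaus && length(step_frames) > 1L) {
    step_frames <- apply_plateau_restriction(step_frames, target, n_frames = nf)
  }
  emitted <- sort(step_frames) - 1L
  heights <- heights[order(order(emitted))]  # arbitrary stable pairing
  ideal <- numeric(nf)
  frames <- seq_len(nf)
  for (i in seq_along(emitted)) ideal <- ideal + heights[i] * (frames <= emitted[i])
  bounds <- unique(step_frames[step_frames >= 2L & step_frames <= nf])
  u_ref <- if (length(heights)) mean(heights) else 1
  eps <- stats::rnorm(nf, 0, u_ref / target)
  realized <- asnr_from_bounds(ideal + eps, bounds)
  if (is.finite(realized) && realized > 0) eps <- eps * (realized / target)
  intensity <- ideal + eps
  structure(list(
    intensity = intensity, frame_duration = spec$frame_duration,
    asnr = asnr_from_bounds(intensity, bounds), target_asnr = target,
    noise_sd = stats::sd(eps), seed = NULL,
    truth = list(step_count = length(step_frames), step_frames = step_frames,
                 step_heights = heights, plateau_means = NULL,
                 n_survivors = 0L, ideal = ideal)
  ), class = "trace_record")
}

#' Robustly normalize a trace for network input
#'
#' Divides by the 99th percentile of the intensity (floored away from
#' zero), so that the initial plateau of a typical trace maps near 1
#' regardless of camera gain. Applied identically at training and
#' prediction time.
#'
#' @param x Numeric vector or matrix (traces in rows).
#' @return Same shape, normalized per trace.
#' @export
normalize_trace <- function(x) {
  if (is.matrix(x)) {
    s <- apply(x, 1L, stats::quantile, probs = 0.99, names = FALSE)
    s <- pmax(abs(s), 1e-9)
    x / s
  } else {
    s <- max(abs(stats::quantile(x, 0.99, names = FALSE)), 1e-9)
    x / s
  }
}
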