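#' Build the step-position network
#'
#' A 1-D convolutional network mapping a 300-sample trace to one
#' activation per time point; trained against multi-hot targets (1 exactly
#' at step frames) with the cosine-similarity loss, so high activations
#' mark likely bleaching time points. Default stack: 4 conv layers of
#' widths 16/32/32/16 (kernel 9) and a linear 1-channel output; the
#' full temporal resolution is preserved (no pooling), so activation
#' indices map one-to-one to trace frames.
#'
#' @param input_len Trace length (300).
#' @param widths,kernel Convolution stack shape.
#' @param seed Weight-initialization seed.
#' @return A `"posnet_model"`.
#' @export
build_position_model <- function(input_len = 300L, widths = c(16L, 32L, 32L, 16L),
                                 kernel = 9L, seed = 1L) {
  layers <- lapply(widths, function(w) layer_conv1d(w, kernel))
  layers <- c(layers, list(layer_conv1d(1L, 1L, activation = "linear")))
  net <- nn_build(layers, input_len, head = "cosine", seed = seed)
  structure(list(net = net, input_len = input_len, history = NULL),
            class = "posnet_model")
}

multi_hot <- function(step_frames, len) {
  v <- numeric(len)
  v[pmin(pmax(step_frames, 1L), len)] <- 1
  v
}

#' Train the step-position network
#'
#' Training traces have step time points drawn uniformly over the trace
#' (a rectangular distribution in the time domain, avoiding positional
#' class imbalance) with 1-4 steps each; targets are multi-hot encoded and
#' the model minimizes the cosine-similarity loss (best-on-validation
#' weights are kept).
#'
#' @param model A `"posnet_model"`.
#' @param n_traces Number of training traces.
#' @param epochs,batch_size,lr Optimization settings.
#' @param step_model,target_asnr Simulation settings.
#' @param val_fraction Fraction held out for validation.
#' @param seed Master seed.
#' @param verbose Print progress.
#' @return The model with trained weights and history.
#' @export
train_position_model <- function(model, n_traces = 8000L, epochs = 4L,
                                 batch_size = 128L, lr = 1e-3,
                                 step_model = "constant_pm20",
                                 target_asnr = c(3, 10),
                                 val_fraction = 0.1, seed = 1L,
                                 verbose = FALSE) {
  stopifnot(inherits(model, "posnet_model"))
  dat <- position_training_batch(n_traces, model$input_len, step_model,
                                 target_asnr, seed = derive_seed(seed, "posdata"))
  n_val <- max(10L, round(val_fraction * n_traces))
  vi <- seq_len(n_val)
  fit <- nn_train(model$net, dat$x[-vi, , drop = FALSE], dat$target[-vi, , drop = FALSE],
                  dat$x[vi, , drop = FALSE], dat$target[vi, , drop = FALSE],
                  epochs = epochs, batch_size = batch_size, lr = lr,
                  seed = derive_seed(seed, "posopt"), verbose = verbose)
  model$net <- fit$model
  model$history <- fit$history
  model
}

# traces with uniformly distributed step positions plus multi-hot targets
position_training_batch <- function(n, input_len, step_model, target_asnr, seed) {
  set.seed(seed)
  x <- matrix(0, n, input_len)
  tg <- matrix(0, n, input_len)
  sf <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(1:4, 1L)
    spec <- trace_sim_spec(k, n_frames = input_len, step_model = step_model,
                           target_asnr = target_asnr)
    tr <- uniform_position_trace(spec)
    x[i, ] <- tr$intensity
    tg[i, ] <- multi_hot(tr$truth$step_frames, input_len)
    sf[[i]] <- tr$truth$step_frames
  }
  list(x = normalize_trace(x), target = tg, step_frames = sf)
}

#' Activation profile of the position network for traces
#'
#' @param model A trained `"posnet_model"`.
#' @param traces Matrix (rows), vector, or `"trace_record"`.
#' @return Matrix of non-negative activations, one row per trace.
#' @export
predict_positions <- function(model, traces) {
  x <- traces_to_matrix(traces, model$input_len)
  pmax(nn_predict(model$net, normalize_trace(x)), 0)
}

#' Select k step frames from an activation profile
#'
#' Takes the top `2k` activation indices, collapses runs of consecutive
#' indices to the run's maximum (wide peaks otherwise beat separate weaker
#' peaks and misplace steps), then keeps the top `k` surviving distinct
#' peaks, sorted. If fewer than `k` distinct peaks exist, all are returned
#' with `shortfall = TRUE`.
#'
#' @param activations Numeric vector (one trace's activations).
#' @param k Step count (>= 1).
#' @return List with `frames` (sorted, 1-based), `shortfall`.
#' @export
locate_steps <- function(activations, k) {
  stopifnot(k >= 1, all(is.finite(activations)))
  n <- length(activations)
  top2k <- order(activations, decreasing = TRUE)[seq_len(min(2L * k, n))]
  idx <- sort(top2k)
  # collapse runs of consecutive indices, keeping each run's maximum
  run_id <- cumsum(c(1L, diff(idx) > 1L))
  peaks <- vapply(split(idx, run_id), function(ii)
    ii[which.max(activations[ii])], integer(1))
  peaks <- peaks[order(activations[peaks], decreasing = TRUE)]
  sel <- peaks[seq_len(min(k, length(peaks)))]
  list(frames = sort(unname(sel)), shortfall = length(peaks) < k)
}

#' Fit plateau means between step frames
#'
#' Segments the trace at the given step frames (each the first frame of a
#' new plateau), takes the mean of each plateau, and returns the
#' piecewise-constant fitted trace. This is the least-squares
#' piecewise-constant fit for the given breakpoints.
#'
#' @param trace Numeric vector or `"trace_record"`.
#' @param step_frames Strictly increasing 1-based frames in `[2, n]`
#'   (may be empty for a step-free trace).
#' @return A `"step_fit_result"`: `step_frames`, `plateau_means`,
#'   `fitted_trace`.
#' @export
fit_plateaus <- function(trace, step_frames) {
  x <- if (inherits(trace, "trace_record")) trace$intensity else as.numeric(trace)
  n <- length(x)
  sf <- as.integer(step_frames)
  if (length(sf)) {
    if (any(duplicated(sf))) stop("duplicate step frames give a zero-length plateau")
    if (is.unsorted(sf, strictly = TRUE)) sf <- sort(sf)
    if (any(sf < 2L) || any(sf > n)) stop("step frames out of range")
  }
  seg <- c(1L, sf, n + 1L)
  means <- numeric(length(seg) - 1L)
  fitted <- numeric(n)
  for (i in seq_along(means)) {
    ii <- seg[i]:(seg[i + 1L] - 1L)
    means[i] <- mean(x[ii])
    fitted[ii] <- means[i]
  }
  structure(list(step_frames = sf, plateau_means = means,
                 fitted_trace = fitted), class = "step_fit_result")
}

#' Legacy moving-average step locator
#'
#' The superseded pre-network method: scans a moving-average difference
#' across the trace and takes the top `k` largest change points (with a
#' minimum separation of one window). Kept for comparison with the
#' position network.
#'
#' @param trace Numeric vector or `"trace_record"`.
#' @param k Number of steps to place.
#' @param window Moving-average half-window (frames).
#' @return Sorted step frames (1-based).
#' @export
moving_avg_steps <- function(trace, k, window = 8L) {
  x <- if (inherits(trace, "trace_record")) trace$intensity else as.numeric(trace)
  n <- length(x)
  stopifnot(k >= 1, n > 2L * window)
  score <- numeric(n)
  for (t in (window + 1L):(n - window + 1L)) {
    score[t] <- mean(x[(t - window):(t - 1L)]) - mean(x[t:(t + window - 1L)])
  }
  chosen <- integer(0)
  s <- score
  for (j in seq_len(k)) {
    b <- which.max(s)
    if (s[b] <= -Inf) break
    chosen <- c(chosen, b)
    s[max(1L, b - window):min(n, b + window)] <- -Inf
  }
  sort(chosen)
}

#' Within-one-frame hit rate of located steps
#'
#' Fraction of true steps matched by a located step within `tol` frames
#' (greedy one-to-one matching).
#'
#' @param located,truth Lists of step-frame vectors (same length).
#' @param tol Tolerance in frames (default 1).
#' @return Fraction in `[0, 1]`.
#' @export
step_hit_rate <- function(located, truth, tol = 1L) {
  hits <- 0L; total <- 0L
  for (i in seq_along(truth)) {
    tv <- truth[[i]]; lv <- located[[i]]
    total <- total + length(tv)
    for (t in tv) {
      if (!length(lv)) next
      j <- which.min(abs(lv - t))
      if (abs(lv[j] - t) <= tol) {
        hits <- hits + 1L
        lv <- lv[-j]
      }
    }
  }
  if (total == 0L) return(NA_real_)
  hits / total
}
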