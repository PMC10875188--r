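#' Configuration of the step-count classifier
#'
#' A compact convolutional-recurrent network: a stack of 1-D convolutions
#' (with max-pooling) extracts local step features, a 128-unit LSTM
#' integrates them over the trace (ignoring e.g. photo-blinking, which
#' shows up as an upward step mirrored by a downward one), a 50% dropout
#' layer regularizes training, and a multilayer perceptron classifies the
#' trace into seven classes (0-4, "5+", "undefined"). The default shapes
#' give about 220K trainable parameters.
#'
#' @param input_len Input trace length (300).
#' @param conv_filters,conv_kernels,pool_sizes Convolution stack shapes
#'   (equal length; each conv is followed by a max-pool of the given
#'   size, so the default collapses 300 samples to 18 recurrent steps).
#' @param lstm_units Recurrent feature width (128).
#' @param dense_units Perceptron widths after the LSTM.
#' @param dropout_rate Dropout between LSTM and perceptron.
#' @return A `"crnn_config"` object.
#' @export
crnn_config <- function(input_len = 300L,
                        conv_filters = c(16L, 32L, 80L),
                        conv_kernels = c(9L, 7L, 5L),
                        pool_sizes = c(2L, 2L, 4L),
                        lstm_units = 128L,
                        dense_units = c(384L, 128L),
                        dropout_rate = 0.5) {
  stopifnot(length(conv_filters) == length(conv_kernels),
            length(pool_sizes) == length(conv_filters), input_len >= 8,
            dropout_rate >= 0, dropout_rate < 1)
  structure(as.list(environment()), class = "crnn_config")
}

#' Build the step-count network
#'
#' @param cfg A [crnn_config()].
#' @param seed Seed for weight initialization.
#' @return A `"crnn_model"` with fields `net`, `cfg`, `labels`, `history`.
#' @export
build_model <- function(cfg = crnn_config(), seed = 1L) {
  layers <- list()
  tl <- cfg$input_len
  for (i in seq_along(cfg$conv_filters)) {
    layers <- c(layers, list(layer_conv1d(cfg$conv_filters[i], cfg$conv_kernels[i]),
                             layer_maxpool(cfg$pool_sizes[i])))
    tl <- tl %/% cfg$pool_sizes[i]
    if (tl < 2L) stop("conv/pool stack incompatible with input_len")
  }
  layers <- c(layers, list(layer_lstm(cfg$lstm_units),
                           layer_dropout(cfg$dropout_rate)))
  for (u in cfg$dense_units) layers <- c(layers, list(layer_dense(u)))
  layers <- c(layers, list(layer_dense(7L, activation = "linear")))
  net <- nn_build(layers, cfg$input_len, head = "softmax", seed = seed)
  structure(list(net = net, cfg = cfg, labels = step_class_labels(),
                 history = NULL), class = "crnn_model")
}

#' Training settings for the step-count network
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 1e-4 and sparse categorical cross-entropy, streaming shards of traces,
#' checkpointing only on validation-accuracy improvement. The `"fast"`
#' preset used by the package's evaluation scripts trains far fewer traces
#' with a larger learning rate (1e-3) to fit a desk-scale budget; expect
#' some accuracy degradation relative to a full-scale run.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size Optimization settings.
#' @param shard_size Traces per generated shard at full scale.
#' @return A `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 10L,
                         batch_size = 512L, shard_size = 240000L) {
  stopifnot(learning_rate > 0)
  structure(as.list(environment()), class = "train_config")
}

#' Fluorophore simulation presets
#'
#' `"Cy5"` uses constant step heights +/- 20% (organic dye); `"mCherry"`
#' and `"mEGFP"` draw step heights from the squared-cosine dipole
#' orientation distribution typical of surface-immobilized protein
#' fluorophores.
#'
#' @param name One of `"Cy5"`, `"mCherry"`, `"mEGFP"`.
#' @return List with `step_model` and a default `target_asnr` range.
#' @export
fluorophore_profile <- function(name = c("Cy5", "mCherry", "mEGFP")) {
  name <- match.arg(name)
  switch(name,
    Cy5 = list(step_model = "constant_pm20",
               target_asnr = list(ranges = list(c(1, 10), c(10, 30)),
                                  weights = c(0.7, 0.3))),
    mCherry = list(step_model = "cos2", target_asnr = c(1, 8)),
    mEGFP = list(step_model = "cos2", target_asnr = c(1, 10)))
}

#' Train the step-count classifier on simulated traces
#'
#' Generates a class-balanced training stream from the simulator (with the
#' training-only plateau length restriction active so that unresolvably
#' close steps do not teach the model to overpredict), trains with Adam /
#' cross-entropy, and keeps the best-on-validation weights.
#'
#' The default training signal-to-noise distribution is a mixture: 70%
#' uniform over aSNR 1-10 (the hard regime where counting is genuinely
#' ambiguous) and 30% uniform over 10-30 (bright dye-like traces, as
#' extracted from well-exposed movies). Networks miscalibrate badly on
#' signal-to-noise regimes absent from training, so the training set must
#' cover every regime the pipeline will encounter.
#'
#' @param model A `"crnn_model"` from [build_model()].
#' @param n_per_class Training traces per class.
#' @param cfg A [train_config()].
#' @param step_model,target_asnr,bleach_prob Simulation settings (see
#'   [simulate_trace_batch()]).
#' @param val_per_class Validation traces per class.
#' @param seed Master seed (data generation, shuffling, dropout).
#' @param checkpoint_path Optional RDS checkpoint, updated only on
#'   validation improvement.
#' @param verbose Print progress.
#' @return The model with trained weights and a `history` data frame.
#' @export
train_crnn <- function(model, n_per_class = 6000L, cfg = train_config(),
                       step_model = "constant_pm20",
                       target_asnr = list(ranges = list(c(1, 10), c(10, 30)), weights = c(0.7, 0.3)),
                       bleach_prob = 1 - 2^(-1 / 40.5),
                       val_per_class = 300L, seed = 1L,
                       checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "crnn_model"))
  tr <- simulate_trace_batch(n_per_class, seed = derive_seed(seed, "train"),
                             n_frames = model$cfg$input_len,
                             step_model = step_model, target_asnr = target_asnr,
                             bleach_prob = bleach_prob, restrict_plateaus = TRUE)
  va <- simulate_trace_batch(val_per_class, seed = derive_seed(seed, "val"),
                             n_frames = model$cfg$input_len,
                             step_model = step_model, target_asnr = target_asnr,
                             bleach_prob = bleach_prob, restrict_plateaus = TRUE)
  fit <- nn_train(model$net, normalize_trace(tr$x), tr$label,
                  normalize_trace(va$x), va$label,
                  epochs = cfg$epochs, batch_size = cfg$batch_size,
                  lr = cfg$learning_rate, seed = derive_seed(seed, "opt"),
                  checkpoint_path = checkpoint_path, verbose = verbose)
  model$net <- fit$model
  model$history <- fit$history
  model$val_accuracy <- fit$best_metric
  model
}

#' Predict photobleaching step counts for traces
#'
#' Traces are resampled to the network's 300-point input domain if needed,
#' robustly normalized, and classified. The "undefined" label is expected
#' whenever the final plateau mean stays materially above zero (a
#' surviving fluorophore).
#'
#' @param model A trained `"crnn_model"`.
#' @param traces Matrix (traces in rows), numeric vector, or
#'   `"trace_record"`.
#' @return Data frame with `label` (factor), `step_count` (integer, `NA`
#'   for "undefined", 5 for "5+"), and class probability columns
#'   `p_0` ... `p_undefined`. The attribute `"features"` holds the
#'   128-dimensional LSTM feature vectors (diagnostics).
#' @export
predict_steps <- function(model, traces) {
  stopifnot(inherits(model, "crnn_model"))
  x <- traces_to_matrix(traces, model$cfg$input_len)
  if (any(!is.finite(x))) stop("traces contain non-finite values")
  logits <- nn_predict(model$net, normalize_trace(x))
  z <- logits - apply(logits, 1L, max)
  p <- exp(z) / rowSums(exp(z))
  colnames(p) <- paste0("p_", sub("\\+", "plus", model$labels))
  lab_idx <- max.col(p)
  label <- factor(model$labels[lab_idx], levels = model$labels)
  step_count <- c(0:4, 5L, NA_integer_)[lab_idx]
  out <- data.frame(label = label, step_count = step_count)
  out <- cbind(out, as.data.frame(p))
  attr(out, "features") <- lstm_features(model$net, normalize_trace(x))
  out
}

traces_to_matrix <- function(traces, input_len) {
  if (inherits(traces, "trace_record")) traces <- traces$intensity
  if (is.numeric(traces) && is.null(dim(traces))) traces <- matrix(traces, nrow = 1L)
  stopifnot(is.matrix(traces))
  if (ncol(traces) != input_len) {
    traces <- t(apply(traces, 1L, resample_trace, target_len = input_len))
  }
  traces
}

# 128-dimensional output of the LSTM layer (the model's feature extractor)
lstm_features <- function(net, x, batch_size = 512L) {
  li <- which(vapply(net$layers, function(l) l$type == "lstm", logical(1)))[1]
  n <- nrow(x)
  out <- NULL
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    fwd <- nn_forward(net, x[idx, , drop = FALSE], train = FALSE)
    st <- fwd$caches[[li]]$steps
    h <- st[[length(st)]]$o * tanh(st[[length(st)]]$c)
    if (is.null(out)) out <- matrix(0, n, ncol(h))
    out[idx, ] <- h
  }
  out
}

#' Evaluate step-count accuracy across signal-to-noise ratios
#'
#' Generates seeded test sets with fully stochastic bleaching (simultaneous
#' bleaching events allowed — the irreducible error source), one bin per
#' requested aSNR, and reports per-bin accuracy, the under/over-prediction
#' split, and a confusion matrix.
#'
#' @param model A trained `"crnn_model"`.
#' @param target_asnrs Numeric vector of aSNR bins.
#' @param n_per_class Test traces per class per bin.
#' @param seed Seed.
#' @param step_model,bleach_prob,n_frames Test simulation settings.
#' @return List with `table` (data frame: `asnr`, `accuracy`, `n`,
#'   `under_frac`, `over_frac`) and `confusion` (list of matrices).
#' @export
evaluate_accuracy <- function(model, target_asnrs = c(1.105, 2, 3.5, 5, 8.853),
                              n_per_class = 100L, seed = 1L,
                              step_model = "constant_pm20",
                              bleach_prob = 1 - 2^(-1 / 40.5),
                              n_frames = 300L) {
  tab <- data.frame()
  conf <- list()
  for (bi in seq_along(target_asnrs)) {
    a <- target_asnrs[bi]
    te <- simulate_trace_batch(n_per_class, seed = derive_seed(seed, paste0("bin", bi)),
                               n_frames = n_frames, step_model = step_model,
                               target_asnr = a, bleach_prob = bleach_prob,
                               restrict_plateaus = FALSE)
    pr <- predict_steps(model, te$x)
    truth <- factor(step_class_labels()[te$label + 1L], levels = step_class_labels())
    acc <- mean(pr$label == truth)
    cm <- table(truth = truth, predicted = pr$label)
    # under/over split among misclassified countable traces
    ti <- te$label; pi <- as.integer(pr$label) - 1L
    err <- which(ti != pi & ti <= 5L & pi <= 5L)
    tab <- rbind(tab, data.frame(
      asnr = a, accuracy = acc, n = length(ti),
      under_frac = if (length(err)) mean(pi[err] < ti[err]) else NA_real_,
      over_frac = if (length(err)) mean(pi[err] > ti[err]) else NA_real_))
    conf[[bi]] <- cm
  }
  list(table = tab, confusion = conf)
}
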