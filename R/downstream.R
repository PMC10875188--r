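#' Infer complex stoichiometry from a step-count histogram
#'
#' Under a binomial labelling model — `N` binding sites, each labelled
#' with probability `p` — the observed distribution of photobleaching step
#' counts follows `Binomial(N, p)`. For each candidate `N` the maximum-
#' likelihood `p` is profiled; `N_hat` is the candidate with the highest
#' profile likelihood, and the reported confidence is the normalized
#' profile likelihood over the candidate range (a declared definition —
#' the quantity is not standardized).
#'
#' Complexes with zero labelled subunits are invisible in real data, so by
#' default the 0-step bin is excluded and the binomial is conditioned on
#' at least one label; set `include_zero = TRUE` when the 0 bin is
#' observable (e.g. simulation ground truth). The "undefined" class is
#' always excluded.
#'
#' When the histogram comes from an imperfect step classifier, pass its
#' confusion matrix (see [classifier_confusion()], estimated on synthetic
#' traces with known ground truth): the binomial class probabilities are
#' then folded through the confusion matrix before comparison, so
#' systematic mis-counting no longer rules out the true `N`. Without a
#' confusion matrix the histogram is taken at face value, and any count
#' in a bin above a candidate `N` excludes that candidate outright.
#'
#' @param hist Named counts with names among `"0" ... "4", "5+"` (a table,
#'   named vector, or the output of [step_histogram()]).
#' @param N_range Candidate `N` values (default 1..8).
#' @param include_zero Include the 0-step bin in the likelihood.
#' @param confusion Optional row-stochastic confusion matrix over the
#'   seven step classes (rows = truth, columns = prediction).
#' @return A `"stoichiometry_inference"`: `N_hat`, `p_hat`, `confidence`,
#'   `per_N` (data frame `N`, `p_hat`, `logLik`, `confidence`),
#'   `degenerate`.
#' @export
infer_stoichiometry <- function(hist, N_range = 1:8, include_zero = FALSE,
                                confusion = NULL) {
  cnt <- as_step_counts(hist)
  if (!include_zero) cnt["0"] <- 0
  counts <- cnt[cnt > 0]
  total <- sum(counts)
  if (total < 30) stop("at least 30 classified traces are required")
  jmax <- function(nm) if (nm == "5+") 5L else as.integer(nm)
  obs_j <- vapply(names(counts), jmax, integer(1))

  cls <- step_class_labels()
  if (!is.null(confusion)) {
    stopifnot(is.matrix(confusion), nrow(confusion) == 7L, ncol(confusion) == 7L)
  }

  # true-class probabilities (over "0".."5+") under binomial(N, p),
  # conditioned on >= 1 visible label unless include_zero
  true_probs <- function(N, p) {
    pj <- c(stats::dbinom(0:4, N, p),
            if (N >= 5L) sum(stats::dbinom(5:N, N, p)) else 0)
    if (!include_zero) {
      pj[1] <- 0
      if (sum(pj) > 0) pj <- pj / sum(pj)
    }
    pj
  }

  loglik_Np <- function(N, p) {
    pj <- true_probs(N, p)
    if (!is.null(confusion)) {
      # fold through the classifier: observed bin probabilities
      po <- as.numeric(c(pj, 0) %*% confusion)   # over the 7 predicted classes
      po <- po[match(names(counts), cls)]
      po <- po / sum(po)                         # renormalize to observed bins
    } else {
      po <- pj[match(names(counts), c("0", "1", "2", "3", "4", "5+"))]
    }
    # floor keeps the objective finite for the optimizer; impossible
    # candidates are screened out before optimization
    sum(counts * log(pmax(po, 1e-300)))
  }

  per_N <- data.frame()
  for (N in N_range) {
    if (is.null(confusion)) {
      # without an error model, observed counts above N exclude it outright
      impossible <- max(obs_j[counts > 0 & names(counts) != "5+"], -Inf) > N ||
        (any(names(counts)[counts > 0] == "5+") && N < 5L)
      if (impossible) {
        per_N <- rbind(per_N, data.frame(N = N, p_hat = NA_real_, logLik = -Inf))
        next
      }
    }
    op <- stats::optimize(function(p) loglik_Np(N, p), c(1e-4, 1 - 1e-4),
                          maximum = TRUE)
    per_N <- rbind(per_N, data.frame(N = N, p_hat = op$maximum,
                                     logLik = op$objective))
  }
  ll <- per_N$logLik
  w <- exp(ll - max(ll[is.finite(ll)]))
  w[!is.finite(ll)] <- 0
  per_N$confidence <- w / sum(w)
  best <- which.max(per_N$confidence)
  structure(list(
    N_hat = per_N$N[best], p_hat = per_N$p_hat[best],
    confidence = per_N$confidence[best], per_N = per_N,
    degenerate = sum(counts > 0) <= 1L), class = "stoichiometry_inference")
}

#' Estimate the step classifier's confusion matrix on synthetic traces
#'
#' Generates a class-balanced batch of traces with known ground truth in
#' the given signal-to-noise regime, classifies them, and returns the
#' row-stochastic confusion matrix (rows = true class, columns =
#' predicted class). Used to fold classifier error into
#' [infer_stoichiometry()].
#'
#' @param model A trained `"crnn_model"`.
#' @param target_asnr aSNR regime of the traces to be analysed.
#' @param n_per_class Traces per class.
#' @param seed Seed.
#' @param step_model,bleach_prob Simulation settings.
#' @return A 7 x 7 row-stochastic matrix over [step_class_labels()].
#' @export
classifier_confusion <- function(model, target_asnr = c(12, 28),
                                 n_per_class = 150L, seed = 1L,
                                 step_model = "constant_pm20",
                                 bleach_prob = 1 - 2^(-1 / 40.5)) {
  te <- simulate_trace_batch(n_per_class, seed = seed,
                             step_model = step_model,
                             target_asnr = target_asnr,
                             bleach_prob = bleach_prob,
                             restrict_plateaus = FALSE)
  pr <- predict_steps(model, te$x)
  truth <- factor(step_class_labels()[te$label + 1L],
                  levels = step_class_labels())
  M <- table(truth, pr$label)
  M <- M / pmax(rowSums(M), 1L)
  unclass(as.matrix(M))
}

as_step_counts <- function(hist) {
  cls <- c("0", "1", "2", "3", "4", "5+")
  if (inherits(hist, "table")) hist <- stats::setNames(as.numeric(hist), names(hist))
  if (is.data.frame(hist)) hist <- stats::setNames(hist$count, hist$class)
  out <- stats::setNames(numeric(length(cls)), cls)
  common <- intersect(names(hist), cls)
  out[common] <- as.numeric(hist[common])
  out
}

#' Step-count histogram from classifier predictions
#'
#' @param predictions Output of [predict_steps()] (or a factor of labels).
#' @return Table of counts over the seven step classes.
#' @export
step_histogram <- function(predictions) {
  lab <- if (is.data.frame(predictions)) predictions$label else predictions
  table(factor(lab, levels = step_class_labels()))
}

#' Two-state FRET analysis of a donor/acceptor trace pair
#'
#' Computes the per-frame FRET efficiency `E = I_A / (I_A + I_D)` from
#' background-subtracted traces, fits the same Gaussian mixture model used
#' for diffusivity deconvolution (1 or 2 components, BIC-selected unless
#' `n_states` is given), hard-assigns frames by posterior, and absorbs
#' dwells shorter than `min_dwell` frames into their neighbours. Assuming
#' a first-order process, the exit rate of each state is the reciprocal of
#' its mean dwell time (censored first and last dwells excluded).
#'
#' @param donor_trace,acceptor_trace Equal-length numeric vectors
#'   (background-subtracted).
#' @param min_dwell Minimum dwell length in frames (default 4).
#' @param frame_duration Seconds per frame.
#' @param n_states Force the number of states (1 or 2), or `NULL` for
#'   BIC selection.
#' @return A `"fret_result"`: `efficiency`, `states` (per-frame integer,
#'   `NA` where total intensity <= 0), `components`, `n_states`,
#'   `dwell_frames` (list per state), `rates` (per second), and
#'   `n_transitions`.
#' @export
detect_fret_states <- function(donor_trace, acceptor_trace, min_dwell = 4L,
                               frame_duration = 0.1, n_states = NULL) {
  stopifnot(length(donor_trace) == length(acceptor_trace))
  tot <- donor_trace + acceptor_trace
  valid <- is.finite(tot) & tot > 0
  E <- rep(NA_real_, length(tot))
  E[valid] <- acceptor_trace[valid] / tot[valid]
  ev <- E[valid]
  gm <- fit_gmm(ev, n_components = n_states, max_components = 2L)
  k <- nrow(gm$components)
  states <- rep(NA_integer_, length(tot))
  if (k == 1L) {
    states[valid] <- 1L
  } else {
    dens <- vapply(seq_len(k), function(i)
      gm$components$weight[i] *
        stats::dnorm(ev, gm$components$mean[i], max(gm$components$sd[i], 1e-6)),
      numeric(length(ev)))
    states[valid] <- max.col(dens)
    states <- merge_short_dwells(states, min_dwell)
  }
  sv <- states[valid]
  r <- rle(sv)
  dwell_frames <- vector("list", k)
  rates <- rep(NA_real_, k)
  if (length(r$lengths) > 2L) {
    inner <- 2:(length(r$lengths) - 1L)   # exclude censored first/last dwells
    for (s in seq_len(k)) {
      dw <- r$lengths[inner][r$values[inner] == s]
      dwell_frames[[s]] <- dw
      if (length(dw)) {
        mean_corr <- max(mean(dw) - (min_dwell - 1L), 1)
        rates[s] <- 1 / (mean_corr * frame_duration)
      }
    }
  }
  structure(list(efficiency = E, states = states, components = gm$components,
                 n_states = k, dwell_frames = dwell_frames, rates = rates,
                 n_transitions = max(0L, length(r$lengths) - 1L)),
            class = "fret_result")
}

# absorb runs shorter than min_dwell into the neighbouring (longer) run
merge_short_dwells <- function(states, min_dwell) {
  ok <- !is.na(states)
  s <- states[ok]
  repeat {
    r <- rle(s)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_dwell)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1L) r$lengths[i - 1L] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    r$values[i] <- if (left >= right) r$values[max(i - 1L, 1L)]
                   else r$values[i + 1L]
    s <- inverse.rle(r)
  }
  states[ok] <- s
  states
}
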