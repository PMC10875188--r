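#' Analyse one channel stack end to end
#'
#' Composite projection of the opening frames, spot enhancement
#' (`"wavelet"` matched-kernel correlation or `"highpass"` Gaussian
#' subtraction), spot detection, trace extraction from the raw stack, and
#' (given a trained model) step-count prediction; with a position model,
#' step positions and plateau fits are added for traces classified with
#' 1-5 steps.
#'
#' @param stack An [image_stack()].
#' @param model Optional trained `"crnn_model"`.
#' @param position_model Optional trained `"posnet_model"`.
#' @param params A [detect_params()].
#' @param enhance `"wavelet"` or `"highpass"`.
#' @param fraction Projection fraction (see [composite_projection()]).
#' @return List with `composite`, `enhanced`, `spots`, `traces` (matrix,
#'   one column per spot), `predictions`, `step_fits` (list or `NULL`).
#' @export
analyze_stack <- function(stack, model = NULL, position_model = NULL,
                          params = detect_params(), enhance = c("wavelet", "highpass"),
                          fraction = 0.2) {
  enhance <- match.arg(enhance)
  comp <- composite_projection(stack, fraction)
  enh <- if (enhance == "wavelet") wavelet_enhance(comp, sigma1 = params$psf_sigma)
         else highpass(comp)
  spots <- detect_spots(enh, params, raw_frame = stack$frames[, , 1])
  res <- list(composite = comp, enhanced = enh, spots = spots,
              traces = NULL, predictions = NULL, step_fits = NULL)
  if (nrow(spots) == 0L) return(res)
  ext <- extract_traces(stack, spots)
  keep <- !ext$flagged
  res$traces <- ext$traces[, keep, drop = FALSE]
  res$spots <- spots[keep, , drop = FALSE]
  if (!is.null(model)) {
    res$predictions <- predict_steps(model, t(res$traces))
    if (!is.null(position_model)) {
      acts <- predict_positions(position_model, t(res$traces))
      res$step_fits <- lapply(seq_len(nrow(res$predictions)), function(i) {
        k <- res$predictions$step_count[i]
        if (is.na(k) || k < 1L) return(NULL)
        loc <- locate_steps(acts[i, ], k)
        sf <- loc$frames[loc$frames >= 2L]
        fit <- fit_plateaus(res$traces[, i], unique(sf))
        fit$shortfall <- loc$shortfall
        fit
      })
    }
  }
  res
}

#' Run the full multi-channel analysis pipeline
#'
#' For each channel: enhance, detect, extract and classify as in
#' [analyze_stack()]. With two or more channels, spots of every secondary
#' channel are colocalized onto the first channel, solving the
#' chromatic-aberration transform per field automatically. Results are
#' optionally exported as CSV files carrying the package version, seed
#' and configuration hash in header comments.
#'
#' @param channels Named list of [image_stack()] objects (first = reference).
#' @param model,position_model Trained models (optional).
#' @param params A [detect_params()].
#' @param f_factors Named chromatic shift factors per secondary channel
#'   (e.g. `c("488" = 1, "561" = 0.35)` for a 640 nm reference).
#' @param radius Colocalization pairing radius (px).
#' @param out_dir Optional output directory for CSV export.
#' @param seed Seed recorded in outputs.
#' @param enhance Enhancement method.
#' @return List with per-channel results (`channels`), colocalization
#'   results (`colocal`), and the export paths (`files`).
#' @export
run_pipeline <- function(channels, model = NULL, position_model = NULL,
                         params = detect_params(),
                         f_factors = c("488" = 1, "561" = 0.35),
                         radius = 2, out_dir = NULL, seed = NA_integer_,
                         enhance = "wavelet") {
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (is.null(names(channels)))
    names(channels) <- vapply(channels, function(s) s$channel, character(1))
  res <- lapply(channels, analyze_stack, model = model,
                position_model = position_model, params = params,
                enhance = enhance)
  coloc <- list()
  if (length(channels) >= 2L) {
    ref <- res[[1]]$spots
    d <- dim(channels[[1]]$frames)
    for (ch in names(channels)[-1]) {
      F <- unname(f_factors[ch])
      if (is.na(F)) stop("no chromatic shift factor configured for channel ", ch)
      coloc[[ch]] <- solve_transform(ref, res[[ch]]$spots, F = F,
                                     radius = radius, field = c(d[2], d[1]))
    }
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- c(sprintf("fluorosteps %s", as.character(utils::packageVersion("fluorosteps"))),
              sprintf("seed %s", seed),
              sprintf("config %s", config_hash(list(params = unclass(params),
                                                    f_factors = f_factors,
                                                    radius = radius))))
    for (ch in names(res)) {
      if (!is.null(res[[ch]]$spots) && nrow(res[[ch]]$spots)) {
        f <- file.path(out_dir, paste0("spots_", ch, ".csv"))
        write_csv_with_header(res[[ch]]$spots, f, meta)
        files <- c(files, f)
      }
      if (!is.null(res[[ch]]$traces)) {
        f <- file.path(out_dir, paste0("traces_", ch, ".csv"))
        write_csv_with_header(as.data.frame(res[[ch]]$traces), f, meta)
        files <- c(files, f)
      }
      if (!is.null(res[[ch]]$predictions)) {
        f <- file.path(out_dir, paste0("steps_", ch, ".csv"))
        write_csv_with_header(res[[ch]]$predictions, f, meta)
        files <- c(files, f)
      }
    }
    for (ch in names(coloc)) {
      if (isTRUE(coloc[[ch]]$success)) {
        f <- file.path(out_dir, paste0("colocal_", ch, ".json"))
        jsonlite::write_json(c(unclass(coloc[[ch]]$transform),
                               list(n_pairs = coloc[[ch]]$n_pairs,
                                    mean_distance = coloc[[ch]]$mean_distance)),
                             f, auto_unbox = TRUE, digits = NA)
        files <- c(files, f)
      }
    }
  }
  list(channels = res, colocal = coloc, files = files)
}

# short deterministic hash of a configuration list (no extra dependencies)
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% 4294967291)
}

#' Write a CSV with comment-header metadata
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Character vector written as `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_csv_with_header <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste("#", meta), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_with_header()]
#'
#' @param path CSV path.
#' @return Data frame (header comments skipped).
#' @export
read_csv_with_header <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
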