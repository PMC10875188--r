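#' Robust local background around a spot
#'
#' Median of an annulus around the spot, excluding the spot's
#' full-width-half-maximum disc, with pixels more than 3 MAD above the
#' annulus median trimmed first (robustness against neighbouring spots
#' leaking into the annulus). At frame edges the annulus shrinks to the
#' available pixels; a fully clipped annulus yields `NA`.
#'
#' @param frame Raw image (matrix).
#' @param spot One-row data frame with `x`, `y` (and optionally
#'   `sigma_x`/`sigma_y`, defaulting to 1.3 px).
#' @param annulus Inner and outer radii (px).
#' @return Background level per pixel (counts).
#' @export
local_background <- function(frame, spot, annulus = c(4, 8)) {
  px <- annulus_pixels(frame, spot, annulus)
  if (!length(px)) return(NA_real_)
  trimmed_median(px)
}

trimmed_median <- function(px) {
  m <- stats::median(px)
  s <- stats::mad(px)
  keep <- px <= m + 3 * s
  if (!any(keep)) return(m)
  stats::median(px[keep])
}

annulus_indices <- function(dimhw, x, y, annulus, sigma = 1.3) {
  h <- dimhw[1]; w <- dimhw[2]
  ro <- ceiling(annulus[2])
  rows <- max(1L, round(y) - ro):min(h, round(y) + ro)
  cols <- max(1L, round(x) - ro):min(w, round(x) + ro)
  d2 <- outer((rows - y)^2, (cols - x)^2, `+`)
  rf2 <- (1.1774 * sigma)^2
  sel <- d2 >= annulus[1]^2 & d2 <= annulus[2]^2 & d2 > rf2
  ij <- which(sel, arr.ind = TRUE)
  (cols[ij[, 2]] - 1L) * h + rows[ij[, 1]]
}

annulus_pixels <- function(frame, spot, annulus) {
  sig <- mean(c(spot$sigma_x %||% 1.3, spot$sigma_y %||% 1.3), na.rm = TRUE)
  idx <- annulus_indices(dim(frame), spot$x, spot$y, annulus, sig)
  frame[idx]
}

window_indices <- function(dimhw, x, y, half = 2L) {
  h <- dimhw[1]; w <- dimhw[2]
  rows <- (round(y) - half):(round(y) + half)
  cols <- (round(x) - half):(round(x) + half)
  if (any(rows < 1L) || any(rows > h) || any(cols < 1L) || any(cols > w))
    return(NULL)
  as.vector(outer(rows, (cols - 1L) * h, `+`))
}

#' Extract a background-subtracted intensity time trace
#'
#' Per frame, sums the pixels of a fixed window (5 x 5 by default) centred
#' on the rounded spot position and subtracts `window area x` the robust
#' local background from the surrounding annulus. Because the background
#' is subtracted locally every frame, the trace mean after all
#' fluorophores have bleached is zero, which is what lets the classifier
#' decide that a stoichiometry is fully resolved; a surviving fluorophore
#' leaves the final plateau above zero and the stoichiometry undecided.
#'
#' @param stack Raw [image_stack()] (unenhanced).
#' @param spot One-row data frame with `x`, `y` (sub-pixel).
#' @param window Window half-size in px (2 gives 5 x 5).
#' @param annulus Background annulus radii (px).
#' @return A `"trace_record"` with the extracted intensity; `flagged` is
#'   `TRUE` when the spot sits too close to the frame edge.
#' @export
extract_trace <- function(stack, spot, window = 2L, annulus = c(4, 8)) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  nt <- d[3]
  widx <- window_indices(d[1:2], spot$x, spot$y, window)
  if (is.null(widx)) {
    return(structure(list(intensity = rep(NA_real_, nt),
                          frame_duration = stack$frame_duration,
                          asnr = NA_real_, flagged = TRUE, truth = NULL),
                     class = "trace_record"))
  }
  sig <- mean(c(spot$sigma_x %||% 1.3, spot$sigma_y %||% 1.3), na.rm = TRUE)
  aidx <- annulus_indices(d[1:2], spot$x, spot$y, annulus, sig)
  plane <- as.numeric(d[1]) * d[2]
  fr <- stack$frames  # linear indexing into the array; no copy
  npx <- length(widx)
  intensity <- numeric(nt)
  off <- 0
  for (t in seq_len(nt)) {
    bg <- trimmed_median(fr[aidx + off])
    intensity[t] <- sum(fr[widx + off]) - npx * bg
    off <- off + plane
  }
  structure(list(intensity = intensity, frame_duration = stack$frame_duration,
                 asnr = NA_real_, flagged = FALSE, truth = NULL,
                 x = spot$x, y = spot$y),
            class = "trace_record")
}

#' Extract traces for a table of spots
#'
#' @param stack Raw [image_stack()].
#' @param spots Data frame of spots (from [detect_spots()]).
#' @inheritParams extract_trace
#' @return List with `traces` (matrix, one trace per column), `spots`, and
#'   `flagged` (logical, edge spots).
#' @export
extract_traces <- function(stack, spots, window = 2L, annulus = c(4, 8)) {
  nt <- dim(stack$frames)[3]
  tr <- matrix(NA_real_, nrow = nt, ncol = nrow(spots))
  flagged <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    t1 <- extract_trace(stack, spots[i, ], window, annulus)
    tr[, i] <- t1$intensity
    flagged[i] <- isTRUE(t1$flagged)
  }
  colnames(tr) <- sprintf("spot_%03d", seq_len(nrow(spots)))
  list(traces = tr, spots = spots, flagged = flagged)
}
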