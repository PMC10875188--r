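#' Chromatic-aberration transform between two colour channels
#'
#' The apparent shift of a spot due to chromatic aberration is modelled as
#' a radial linear transform about an origin: `dx = F * (x - xc) / Sx`,
#' `dy = F * (y - yc) / Sy`. `F` scales the whole transformation with the
#' wavelength difference (1 for 640 nm -> 488 nm, 0.35 for 640 nm ->
#' 561 nm); `(xc, yc)` is the origin where spots superimpose perfectly;
#' `Sx`, `Sy` are the distances from the origin that produce a 1-pixel
#' shift in each axis.
#'
#' @param F Dimensionless shift factor (>= 0).
#' @param xc,yc Transformation origin (px).
#' @param Sx,Sy Scale factors (px of distance per px of shift; nonzero).
#' @return A `"chromatic_transform"` object.
#' @export
chromatic_transform <- function(F = 1, xc = 256, yc = 256, Sx = 1000, Sy = 1000) {
  stopifnot(F >= 0, Sx != 0, Sy != 0)
  structure(list(F = F, xc = xc, yc = yc, Sx = Sx, Sy = Sy),
            class = "chromatic_transform")
}

#' Apply a chromatic shift to spot coordinates
#'
#' Returns `(x + dx, y + dy)` with `dx = F (x - xc) / Sx` and
#' `dy = F (y - yc) / Sy`; exactly linear in `F` and in the distance from
#' the origin, with the origin itself a fixed point.
#'
#' @param spots Data frame with `x`, `y` (or a length-2 vector).
#' @param transform A [chromatic_transform()].
#' @return Same shape as the input with shifted coordinates.
#' @export
chromatic_shift <- function(spots, transform) {
  stopifnot(inherits(transform, "chromatic_transform"))
  if (is.numeric(spots) && length(spots) == 2L) {
    return(c(spots[1] + transform$F * (spots[1] - transform$xc) / transform$Sx,
             spots[2] + transform$F * (spots[2] - transform$yc) / transform$Sy))
  }
  spots$x <- spots$x + transform$F * (spots$x - transform$xc) / transform$Sx
  spots$y <- spots$y + transform$F * (spots$y - transform$yc) / transform$Sy
  spots
}

#' Pair spots across channels after chromatic correction
#'
#' Transforms channel B onto channel A with the given transform, then pairs
#' spots by greedy mutual nearest neighbours (repeatedly taking the
#' globally closest unpaired A-B pair within `radius`). Each spot
#' participates in at most one pair.
#'
#' @param spots_A,spots_B Data frames with `x`, `y`.
#' @param transform A [chromatic_transform()].
#' @param radius Maximum pair distance after the transform (px).
#' @return A `"colocal_result"`: list with `pairs` (data frame `index_A`,
#'   `index_B`, `distance`), `transform`, `radius`.
#' @export
match_spots <- function(spots_A, spots_B, transform, radius = 2) {
  stopifnot(radius > 0)
  nb <- nrow(spots_B); na <- nrow(spots_A)
  pairs <- data.frame(index_A = integer(0), index_B = integer(0),
                      distance = numeric(0))
  if (na > 0L && nb > 0L) {
    tb <- chromatic_shift(spots_B, transform)
    D <- outer(spots_A$x, tb$x, `-`)^2 + outer(spots_A$y, tb$y, `-`)^2
    repeat {
      i <- which.min(D)
      if (!length(i) || !is.finite(D[i]) || D[i] > radius^2) break
      ai <- (i - 1L) %% na + 1L
      bi <- (i - 1L) %/% na + 1L
      pairs <- rbind(pairs, data.frame(index_A = ai, index_B = bi,
                                       distance = sqrt(D[i])))
      D[ai, ] <- Inf; D[, bi] <- Inf
    }
  }
  structure(list(pairs = pairs, transform = transform, radius = radius),
            class = "colocal_result")
}

# fast one-to-one (mutual nearest neighbour) pair count within radius
mutual_pair_stats <- function(ax, ay, bx, by, radius2) {
  D <- outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2
  jstar <- max.col(-D, ties.method = "first")            # per A row, nearest B
  istar <- max.col(-t(D), ties.method = "first")         # per B col, nearest A
  i <- seq_along(ax)
  d <- D[cbind(i, jstar)]
  ok <- istar[jstar] == i & d <= radius2
  c(sum(ok), if (any(ok)) mean(sqrt(d[ok])) else Inf)
}

#' Solve the chromatic-aberration parameters from one field of view
#'
#' Two-stage auto-calibration used when no calibration file is available.
#' A grid search over transformation origins and scale factors finds the
#' parameters that maximise the number of colocalized spots (the pair
#' count is not a continuous function of the parameters, so gradient-free
#' grid search is required; ties are broken by smaller mean pair
#' distance). A Nelder-Mead simplex then refines the parameters by
#' minimizing the mean distance of the grid-stage pairs, which are held
#' fixed to keep the objective continuous. Only spots within the central
#' half of the field participate (the linear model holds in the central
#' 256 x 256 of a 512 x 512 detector).
#'
#' A minimum of 4 colocalized spots is required for reliable solving;
#' below that the result carries `success = FALSE`.
#'
#' @param spots_A,spots_B Data frames with `x`, `y`.
#' @param F Shift factor, held fixed per channel pair.
#' @param radius Pairing radius (px).
#' @param field `c(width, height)` of the detector (px).
#' @param grid_spacing Origin grid spacing (px).
#' @param s_range,n_s Geometric search range and number of steps for the
#'   scale factors.
#' @param min_pairs Minimum pair count for success.
#' @return List with `transform`, `pairs`, `n_pairs`, `mean_distance`,
#'   `success`.
#' @export
solve_transform <- function(spots_A, spots_B, F = 1, radius = 2,
                            field = c(512, 512), grid_spacing = 8,
                            s_range = c(300, 3000), n_s = 10,
                            min_pairs = 4L) {
  stopifnot(nrow(spots_A) > 0, nrow(spots_B) > 0, radius > 0)
  cx <- field[1] / 2; cy <- field[2] / 2
  inA <- abs(spots_A$x - cx) <= field[1] / 4 & abs(spots_A$y - cy) <= field[2] / 4
  inB <- abs(spots_B$x - cx) <= field[1] / 4 & abs(spots_B$y - cy) <= field[2] / 4
  A <- spots_A[inA, , drop = FALSE]
  B <- spots_B[inB, , drop = FALSE]
  fail <- list(transform = NULL, pairs = NULL, n_pairs = 0L,
               mean_distance = NA_real_, success = FALSE)
  if (nrow(A) == 0L || nrow(B) == 0L) return(fail)

  xc_grid <- seq(cx - field[1] / 4, cx + field[1] / 4, by = grid_spacing)
  yc_grid <- seq(cy - field[2] / 4, cy + field[2] / 4, by = grid_spacing)
  s_grid <- exp(seq(log(s_range[1]), log(s_range[2]), length.out = n_s))
  r2 <- radius^2

  best <- c(-1, Inf); best_par <- NULL
  for (Sx in s_grid) for (Sy in s_grid) {
    fx <- 1 + F / Sx; fy <- 1 + F / Sy
    for (xc in xc_grid) {
      bx <- B$x * fx - F * xc / Sx
      for (yc in yc_grid) {
        by <- B$y * fy - F * yc / Sy
        st <- mutual_pair_stats(A$x, A$y, bx, by, r2)
        if (st[1] > best[1] || (st[1] == best[1] && st[2] < best[2])) {
          best <- st; best_par <- c(xc, yc, Sx, Sy)
        }
      }
    }
  }
  if (is.null(best_par) || best[1] < min_pairs) return(fail)

  tr0 <- chromatic_transform(F, best_par[1], best_par[2], best_par[3], best_par[4])
  m0 <- match_spots(A, B, tr0, radius)
  pa <- m0$pairs
  if (nrow(pa) < min_pairs) return(fail)

  obj <- function(p) {
    tb <- chromatic_shift(B[pa$index_B, , drop = FALSE],
                          chromatic_transform(F, p[1], p[2], p[3], p[4]))
    mean(sqrt((A$x[pa$index_A] - tb$x)^2 + (A$y[pa$index_A] - tb$y)^2))
  }
  opt <- stats::optim(best_par, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  tr <- chromatic_transform(F, opt$par[1], opt$par[2], opt$par[3], opt$par[4])
  final <- match_spots(spots_A, spots_B, tr, radius)
  list(transform = tr, pairs = final$pairs, n_pairs = nrow(final$pairs),
       mean_distance = if (nrow(final$pairs)) mean(final$pairs$distance) else NA_real_,
       success = TRUE)
}
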