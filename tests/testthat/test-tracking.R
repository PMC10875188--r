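make_detections <- function(tracks_xy) {
  # tracks_xy: list of data.frame(frame, x, y)
  do.call(rbind, tracks_xy)
}

test_that("a single emitter yields one full-length track", {
  det <- data.frame(frame = 1:60, x = 20 + cumsum(rnorm(60, 0, 0.3)),
                    y = 30 + cumsum(rnorm(60, 0, 0.3)))
  tks <- link_tracks(det, max_jump = 3, min_len = 10)
  expect_length(tks, 1L)
  expect_equal(nrow(tks[[1]]), 60L)
})

test_that("well-separated emitters never swap identities", {
  set.seed(1)
  t1 <- data.frame(frame = 1:50, x = 10 + cumsum(rnorm(50, 0, 0.2)),
                   y = 10 + cumsum(rnorm(50, 0, 0.2)))
  t2 <- data.frame(frame = 1:50, x = 60 + cumsum(rnorm(50, 0, 0.2)),
                   y = 60 + cumsum(rnorm(50, 0, 0.2)))
  tks <- link_tracks(make_detections(list(t1, t2)), max_jump = 3, min_len = 10)
  expect_length(tks, 2L)
  for (tk in tks) {
    expect_lt(diff(range(tk$x)), 15)  # stayed near one emitter
    expect_equal(nrow(tk), 50L)
  }
})

test_that("a one-frame dropout is bridged within the blink window", {
  det <- data.frame(frame = c(1:20, 22:40), x = 25, y = 25)
  tks <- link_tracks(det, max_jump = 3, blink_window = 1, min_len = 10)
  expect_length(tks, 1L)
  expect_equal(nrow(tks[[1]]), 39L)
  expect_false(21 %in% tks[[1]]$frame)

  # beyond the blink window the molecule restarts as a new track
  det2 <- data.frame(frame = c(1:20, 25:40), x = 25, y = 25)
  tks2 <- link_tracks(det2, max_jump = 3, blink_window = 1, min_len = 5)
  expect_length(tks2, 2L)
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(2)
  t1 <- data.frame(frame = 1:30, x = 10 + cumsum(rnorm(30, 0, 0.3)), y = 10)
  t2 <- data.frame(frame = 1:30, x = 50 + cumsum(rnorm(30, 0, 0.3)), y = 50)
  det <- make_detections(list(t1, t2))
  shuf <- det[order(det$frame, runif(nrow(det))), ]
  k1 <- link_tracks(det, max_jump = 3, min_len = 10)
  k2 <- link_tracks(shuf, max_jump = 3, min_len = 10)
  expect_equal(length(k1), length(k2))
  key <- function(tks) sort(vapply(tks, function(t) sum(t$x) + sum(t$y), numeric(1)))
  expect_equal(key(k1), key(k2), tolerance = 1e-9)
})

test_that("MSD is zero for stationary tracks and exactly quadratic under drift", {
  still <- data.frame(frame = 1:30, x = 5, y = 9)
  expect_true(all(msd_curve(still)$msd == 0))

  v <- 0.7  # px per frame
  drift <- data.frame(frame = 1:40, x = v * (1:40), y = 0)
  m <- msd_curve(drift, frame_duration = 0.1, pixel_size = 0.1)
  # MSD(tau) = (v_um_per_s * tau)^2 with v = 0.7 px/frame = 0.7 um/s
  expect_equal(m$msd, (0.7 * m$tau / 0.1 * 0.1)^2, tolerance = 1e-12)
})

test_that("MSD equals the brute-force double-loop evaluation, gaps included", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(8:25, 1)
    frames <- sort(sample(1:(n + 10), n))
    tk <- data.frame(frame = frames, x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
    a <- msd_curve(tk, 0.08, 0.16)
    b <- msd_bruteforce(tk, 0.08, 0.16)
    expect_equal(a$tau, b$tau, tolerance = 1e-10)
    expect_equal(a$msd, b$msd, tolerance = 1e-10)
    expect_equal(a$n_pairs, b$n_pairs)
  }
})

test_that("a perfectly linear MSD is fitted over its full range with zero spread", {
  tau <- seq(0.1, 2, by = 0.1)
  msd <- data.frame(tau = tau, msd = 4 * 0.05 * tau, n_pairs = 50)
  est <- fit_diffusion(msd)
  expect_equal(est$D, 0.05, tolerance = 1e-12)
  expect_equal(est$fit_fraction, 1)
  expect_lt(est$rel_sd_percent, 1e-6)

  zero <- data.frame(tau = tau, msd = 0, n_pairs = 50)
  ez <- fit_diffusion(zero)
  expect_equal(ez$D, 0)
  expect_equal(ez$rel_sd_percent, 0)
})

test_that("a saturating (confined) tail is excluded from the fitted range", {
  tau <- seq(0.1, 3, by = 0.1)
  msd <- 4 * 0.05 * tau
  msd[tau > 1] <- msd[tau == 1]  # confinement plateau
  est <- fit_diffusion(data.frame(tau = tau, msd = msd, n_pairs = 50))
  expect_lt(est$fit_fraction, 0.5)
  expect_equal(est$D, 0.05, tolerance = 0.01)
})

test_that("a quadratic drift term does not corrupt the drift-free prefix estimate", {
  tau <- seq(0.1, 4, by = 0.1)
  msd <- 4 * 0.02 * tau + (0.05 * tau)^2
  est <- fit_diffusion(data.frame(tau = tau, msd = msd, n_pairs = 50))
  expect_equal(est$D, 0.02, tolerance = 0.10)
})

test_that("ensemble-mean fitted D is unbiased within 5 percent for Brownian tracks", {
  spec <- diffusion_sim_spec(species = data.frame(D = 0.05, count = 500),
                             n_frames = 100, height = 8192, width = 8192)
  tt <- simulate_diffusion_tracks(spec, seed = 4)
  est <- track_diffusion(split(tt, tt$track_id))
  expect_equal(mean(est$D), 0.05, tolerance = 0.05)
})

test_that("track filtering is monotone in the threshold", {
  set.seed(5)
  est <- data.frame(track_id = 1:50, D = runif(50),
                    rel_sd_percent = runif(50, 0, 300))
  k1 <- filter_tracks(est, 4)
  k2 <- filter_tracks(est, 20)
  k3 <- filter_tracks(est, 200)
  expect_true(all(k1$track_id %in% k2$track_id))
  expect_true(all(k2$track_id %in% k3$track_id))
  expect_gt(nrow(k3), nrow(k1))
  expect_equal(nrow(filter_tracks(est, 1e9)), 50L)
})

test_that("the mixture fit recovers two separated diffusivity populations", {
  set.seed(6)
  v <- c(rnorm(250, 0.02, 0.004), rnorm(250, 0.10, 0.01))
  gm <- fit_gmm(v, n_components = 2)
  expect_equal(gm$components$mean, c(0.02, 0.10), tolerance = 0.05)
  expect_equal(sum(gm$components$weight), 1, tolerance = 1e-6)

  g1 <- fit_gmm(rnorm(100, 0.05, 0.01), n_components = 1)
  expect_equal(g1$components$mean, 0.05, tolerance = 0.01)

  gd <- fit_gmm(rep(0.3, 20))
  expect_equal(gd$n_components, 1L)
  expect_equal(gd$components$mean, 0.3)
})

test_that("automatic component selection finds the right order on clean mixtures", {
  set.seed(7)
  v <- c(rnorm(300, 1, 0.05), rnorm(300, 2, 0.05))
  gm <- fit_gmm(v)
  expect_equal(gm$n_components, 2L)
})

test_that("mislocalization decreases with SNR and noiseless spots localize to centipixels", {
  tab <- localization_error_study(snr_grid = c(2, 3, 5, 8), n_per_bin = 120,
                                  seed = 8)
  expect_true(all(diff(tab$mean_error) < 0))
  # heavy right tail in the low-SNR regime where spots vanish into noise
  expect_gt(tab$q99_error[1] / tab$median_error[1], 3)

  clean <- render_frame(32, 32, 16.3, 15.8, amplitude = 10)
  sp <- detect_spots(clean, detect_params(tracking_mode = TRUE))
  expect_equal(nrow(sp), 1L)
  expect_lt(sqrt((sp$x - 16.3)^2 + (sp$y - 15.8)^2), 0.02)
})
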