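test_that("a trace with no emitters is flat zero-mean noise", {
  tr <- simulate_trace(trace_sim_spec(0, target_asnr = 6), seed = 1)
  expect_equal(tr$truth$step_count, 0L)
  expect_length(tr$intensity, 300L)
  expect_lt(abs(mean(tr$intensity)), 3 * sd(tr$intensity) / sqrt(300))
  expect_equal(tr$truth$ideal, rep(0, 300))
})

test_that("constant-hazard bleaching reproduces the geometric lifetime of a 40.5-frame half-life", {
  p <- 1 - 2^(-1 / 40.5)
  # long traces so censoring at the recording end is negligible
  spec <- trace_sim_spec(1, n_frames = 3000L, bleach_prob = p, target_asnr = Inf)
  set.seed(99)
  frames <- replicate(4000, {
    tr <- simulate_trace(spec)
    if (tr$truth$step_count == 1L) tr$truth$step_frames[1] - 1L else NA_integer_
  })
  expect_lt(mean(is.na(frames)), 0.01)
  expect_equal(mean(frames, na.rm = TRUE), 1 / p - 1, tolerance = 0.02)
})

test_that("dye-like step heights are unit +/- 20 percent", {
  set.seed(3)
  for (s in 1:20) {
    tr <- simulate_trace(trace_sim_spec(1, target_asnr = Inf), seed = s)
    if (tr$truth$step_count == 0L) next
    h <- tr$truth$step_heights
    expect_true(all(h >= 0.8 & h <= 1.2))
    # noiseless: the trace drop equals the step height exactly
    expect_equal(tr$intensity[1] - tr$intensity[300], sum(h))
  }
})

test_that("cos2 step heights span the dipole-orientation range with a 10 percent floor", {
  set.seed(4)
  h <- draw_step_heights(5000, "cos2")
  expect_true(all(h >= 0.10 & h <= 1))
  expect_gt(mean(h < 0.2), 0.15)  # substantial weak-emitter tail
})

test_that("aSNR evaluates the plateau formula on constructed plateaus", {
  # plateaus c(m-1, m, m+1) have mean m and sample sd exactly 1
  x2 <- c(9, 10, 11, -1, 0, 1)
  expect_equal(compute_asnr(x2, 4L), 10)
  x3 <- c(1, 2, 3, 0, 1, 2, -1, 0, 1)
  expect_equal(compute_asnr(x3, c(4L, 7L)), 1)
})

test_that("aSNR equals an independent brute-force evaluation on random traces", {
  set.seed(5)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    lens <- sample(3:40, k, replace = TRUE)
    x <- unlist(lapply(seq_len(k), function(j) rnorm(lens[j], mean = k - j)))
    bounds <- cumsum(lens)[-k] + 1L
    expect_equal(compute_asnr(x, bounds), asnr_bruteforce(x, bounds),
                 tolerance = 1e-12)
  }
})

test_that("aSNR flags undefined and infinite cases distinctly", {
  expect_error(compute_asnr(rnorm(50), integer(0)), "no steps")
  expect_error(compute_asnr(rnorm(10), c(5L, 6L)), "at least 2 frames")
  expect_identical(compute_asnr(c(rep(1, 10), rep(0, 10)), 11L), Inf)
})

test_that("aSNR scales inversely with the noise level", {
  set.seed(6)
  ideal <- c(rep(2, 100), rep(1, 100), rep(0, 100))
  ratio <- replicate(1000, {
    eps <- rnorm(300, 0, 0.3)
    compute_asnr(ideal + eps, c(101L, 201L)) /
      compute_asnr(ideal + 2 * eps, c(101L, 201L))
  })
  expect_equal(mean(ratio), 2, tolerance = 0.02)
})

test_that("realized aSNR matches the requested target within a few percent", {
  set.seed(7)
  a <- replicate(300, simulate_trace(trace_sim_spec(2, target_asnr = 4))$asnr)
  expect_equal(mean(a, na.rm = TRUE), 4, tolerance = 0.03)
})

test_that("noiseless post-bleach segments are exactly zero and step sums telescope", {
  set.seed(8)
  for (s in 1:20) {
    tr <- simulate_trace(trace_sim_spec(3, target_asnr = Inf), seed = s)
    if (tr$truth$n_survivors > 0L || tr$truth$step_count == 0L) next
    last <- max(tr$truth$step_frames)
    expect_identical(tr$intensity[last:300], rep(0, 300 - last + 1))
    # fluorophores bleaching before frame 2 never contribute to frame 1
    visible <- tr$truth$step_frames > 1L
    expect_equal(tr$intensity[1], sum(tr$truth$step_heights[visible]))
  }
})

test_that("plateau restriction defers unresolvable steps and is inactive at high aSNR", {
  expect_identical(apply_plateau_restriction(c(40L, 41L), 1.2),
                   c(40L, 58L))  # min separation ceil(25 / 1.44) = 18
  expect_identical(apply_plateau_restriction(c(40L, 200L), 1.2), c(40L, 200L))
  expect_identical(apply_plateau_restriction(c(40L, 41L), 8), c(40L, 41L))
  expect_identical(apply_plateau_restriction(c(40L, 41L), 9.7), c(40L, 41L))
})

test_that("trace resampling is the identity at native length and linear otherwise", {
  x <- rnorm(300)
  expect_equal(resample_trace(x), x)
  expect_equal(resample_trace(c(0, 1)), seq(0, 1, length.out = 300))
  step100 <- c(rep(1, 50), rep(0, 50))
  y <- resample_trace(step100)
  expect_length(y, 300)
  expect_true(any(y > 0.05 & y < 0.95))  # interpolated points between plateaus
  expect_equal(y[1], 1); expect_equal(y[300], 0)
  expect_error(resample_trace(1), "at least 2")
})

test_that("batch generation balances classes and leaves survivors only in the undefined class", {
  b <- simulate_trace_batch(30, seed = 9)
  expect_equal(as.vector(table(b$class)), rep(30L, 7L))
  expect_equal(dim(b$x), c(210L, 300L))
  for (i in which(b$label <= 4L)[1:20]) {
    expect_equal(length(b$step_frames[[i]]), b$label[i])
  }
  for (i in which(b$label == 5L)[1:10]) {
    expect_gte(length(b$step_frames[[i]]), 5L)
  }
  for (i in which(b$label == 6L)[1:10]) {
    expect_lte(length(b$step_frames[[i]]), 4L)  # forced survivor excluded
  }
})

test_that("binomial label counts match the specified pmf", {
  set.seed(10)
  n <- draw_label_counts(10000, list(type = "binomial", size = 3L, prob = 0.4))
  obs <- tabulate(n + 1L, nbins = 4L)
  p <- dbinom(0:3, 3, 0.4)
  expect_gt(chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("a stationary noiseless complex yields a constant extracted trace", {
  spec <- movie_sim_spec(n_complexes = 1, n_frames = 40, height = 64, width = 64,
                         stoichiometry = list(type = "fixed", n = 1),
                         dark_noise_sigma = 0, autofluorescence = 0,
                         gain_shape = Inf, bleach_prob = 1e-12)
  mv <- simulate_movie(spec, seed = 11)
  tr <- extract_trace(mv$stack, mv$truth[1, ])
  expect_false(tr$flagged)
  expect_lt(diff(range(tr$intensity)) / mean(tr$intensity), 1e-6)
})

test_that("movie ground truth records bleach frames consistent with amplitudes", {
  spec <- movie_sim_spec(n_complexes = 12, n_frames = 60, height = 96, width = 96,
                         stoichiometry = list(type = "fixed", n = 2),
                         dark_noise_sigma = 0, autofluorescence = 0,
                         gain_shape = Inf)
  mv <- simulate_movie(spec, seed = 12)
  i <- which(mv$truth$bleach_frames != "")[1]
  bf <- min(as.integer(strsplit(mv$truth$bleach_frames[i], ";")[[1]]))
  if (bf > 1 && bf <= 60) {
    px <- mv$stack$frames[round(mv$truth$y[i]), round(mv$truth$x[i]), ]
    expect_gt(px[bf - 1], px[min(bf + 1, 60)] - 1e-9)
  }
  expect_true(all(mv$truth$n_labels == 2L))
})

test_that("Brownian simulation has the closed-form step size and MSD", {
  spec <- diffusion_sim_spec(species = data.frame(D = 0.1, count = 40),
                             n_frames = 80, height = 512, width = 512)
  tt <- simulate_diffusion_tracks(spec, seed = 13)
  steps <- unlist(lapply(split(tt, tt$track_id), function(d) diff(d$x)))
  # per-axis step sd = sqrt(2 D dt) / pixel_size = 1.414 px
  expect_equal(sd(steps), sqrt(2 * 0.1 * 0.1) / 0.1, tolerance = 0.05)

  z <- diffusion_sim_spec(species = data.frame(D = 0, count = 3), n_frames = 30)
  t0 <- simulate_diffusion_tracks(z, seed = 14)
  tr1 <- t0[t0$track_id == 1, ]
  expect_true(all(msd_curve(tr1)$msd == 0))
})

test_that("ensemble mean MSD follows 4 D tau at small lags", {
  spec <- diffusion_sim_spec(species = data.frame(D = 0.05, count = 500),
                             n_frames = 40, height = 4096, width = 4096)
  tt <- simulate_diffusion_tracks(spec, seed = 15)
  msd5 <- vapply(split(tt, tt$track_id), function(d) {
    m <- msd_curve(d, 0.1, 0.1)
    m$msd[m$tau == 0.5]
  }, numeric(1))
  expect_equal(mean(msd5), 4 * 0.05 * 0.5, tolerance = 0.05)
})

test_that("invalid simulation specs are rejected", {
  expect_error(trace_sim_spec(-1), "non-negative")
  expect_error(trace_sim_spec(1, bleach_prob = 0), "bleach_prob")
  expect_error(trace_sim_spec(1, n_frames = 1), "n_frames")
  expect_error(trace_sim_spec(1, target_asnr = -2), "target_asnr")
  expect_error(place_positions(500, 32, 32, 8, 10), "field too small")
})
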