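test_that("candidate search returns nothing on featureless images", {
  expect_equal(nrow(find_candidates(matrix(0, 64, 64))), 0L)
  set.seed(1)
  flat_noise <- matrix(rnorm(64 * 64), 64, 64)
  # pure noise may produce candidates, but a constant image must not
  expect_equal(nrow(find_candidates(matrix(5, 64, 64))), 0L)
})

test_that("an injected spot yields exactly one nearby candidate, two spots two", {
  set.seed(2)
  img <- render_frame(64, 64, 30.4, 41.7, amplitude = 10, noise_sd = 1)
  cand <- find_candidates(img)
  d <- sqrt((cand$x - 30.4)^2 + (cand$y - 41.7)^2)
  expect_equal(sum(d <= 1.5), 1L)

  img2 <- render_frame(64, 64, c(20, 40), c(32, 32), amplitude = 10, noise_sd = 1)
  cand2 <- find_candidates(img2)
  expect_equal(sum(sqrt((cand2$x - 20)^2 + (cand2$y - 32)^2) <= 1.5), 1L)
  expect_equal(sum(sqrt((cand2$x - 40)^2 + (cand2$y - 32)^2) <= 1.5), 1L)
})

test_that("kernel screening accepts Gaussian spots and rejects hot pixels", {
  g <- render_frame(11, 11, 6, 6, amplitude = 10)
  scr <- kernel_screen(g)
  expect_true(scr$accept)
  expect_lt(scr$residual, 0.01)

  hot <- matrix(0, 11, 11); hot[6, 6] <- 100
  expect_false(kernel_screen(hot)$accept)

  set.seed(3)
  ok <- replicate(500, {
    # amplitude giving a mean-in-FWHM signal-to-noise ratio of 5
    patch <- render_frame(11, 11, 6, 6, amplitude = 5 / 0.7213, noise_sd = 1)
    kernel_screen(patch)$accept
  })
  expect_gte(mean(ok), 0.99)
})

test_that("Gaussian fitting recovers noiseless sub-pixel centres to 0.01 px", {
  patch <- render_frame(11, 11, 5.30, 5.70, amplitude = 8, sigma = 1.3)
  sp <- fit_gaussian(patch)
  expect_true(sp$converged)
  expect_lt(abs(sp$x - 5.30), 0.01)
  expect_lt(abs(sp$y - 5.70), 0.01)
  expect_equal(sp$sigma_x, 1.3, tolerance = 0.01)
  expect_lt(sp$residual, 1e-6)
})

test_that("eccentric blobs report eccentricity above the default threshold", {
  rows <- 1:11; cols <- 1:11
  blob <- outer(exp(-(rows - 6)^2 / (2 * 1^2)), exp(-(cols - 6)^2 / (2 * 3^2))) * 10
  sp <- fit_gaussian(blob)
  expect_gt(sp$eccentricity, detect_params()$eccentricity_max)
})

test_that("full detection achieves high recall and precision on well-separated bright spots", {
  set.seed(4)
  n <- 50
  gx <- rep(seq(12, 116, length.out = 8), length.out = n) +  runif(n, -2, 2)
  gy <- rep(seq(12, 116, length.out = 8), each = 8)[1:n] + runif(n, -2, 2)
  img <- render_frame(128, 128, gx, gy, amplitude = rep(12, n), noise_sd = 1)
  sp <- detect_spots(img)
  matched <- 0L
  for (i in seq_len(n)) {
    if (min((sp$x - gx[i])^2 + (sp$y - gy[i])^2) <= 4) matched <- matched + 1L
  }
  fp <- sum(vapply(seq_len(nrow(sp)), function(j)
    min((gx - sp$x[j])^2 + (gy - sp$y[j])^2) > 4, logical(1)))
  expect_gte(matched / n, 0.98)
  expect_gte(1 - fp / nrow(sp), 0.98)

  expect_equal(nrow(detect_spots(matrix(0, 64, 64))), 0L)
})

test_that("all returned spots satisfy every acceptance threshold", {
  set.seed(5)
  img <- render_frame(96, 96, c(20, 50, 80), c(30, 60, 20), amplitude = 10,
                      noise_sd = 1)
  p <- detect_params()
  sp <- detect_spots(img, p)
  expect_gt(nrow(sp), 0L)
  expect_true(all(sp$sigma_x >= p$sigma_range[1] & sp$sigma_x <= p$sigma_range[2]))
  expect_true(all(sp$sigma_y >= p$sigma_range[1] & sp$sigma_y <= p$sigma_range[2]))
  expect_true(all(sp$eccentricity <= p$eccentricity_max))
  expect_true(all(sp$residual <= p$fit_residual_max))
})

test_that("detection is equivariant to integer image shifts", {
  set.seed(6)
  base <- render_frame(96, 96, c(40.3, 60.8), c(45.6, 30.2), amplitude = 12,
                       noise_sd = 0.5)
  sp1 <- detect_spots(base)
  shifted <- matrix(0, 96, 96)
  shifted[4:96, 6:96] <- base[1:93, 1:91]  # shift by (+3 rows, +5 cols)
  sp2 <- detect_spots(shifted)
  for (i in seq_len(nrow(sp1))) {
    j <- which.min((sp2$x - sp1$x[i] - 5)^2 + (sp2$y - sp1$y[i] - 3)^2)
    expect_lt(abs(sp2$x[j] - sp1$x[i] - 5), 0.05)
    expect_lt(abs(sp2$y[j] - sp1$y[i] - 3), 0.05)
  }
})

test_that("spot SNR matches its analytic expectation and flags degenerate cases", {
  set.seed(7)
  spot <- data.frame(x = 16, y = 16, sigma_x = 1.3, sigma_y = 1.3)
  A <- 8
  snrs <- replicate(500, {
    img <- render_frame(32, 32, 16, 16, amplitude = A, noise_sd = 1)
    spot_snr(img, spot)
  })
  expect_equal(mean(snrs), 0.7213 * A, tolerance = 0.15)

  # flat-top spot on an exactly constant background: zero noise, infinite SNR
  clean <- matrix(5, 32, 32); clean[15:17, 15:17] <- 20
  expect_identical(spot_snr(clean, spot), Inf)

  bg <- matrix(rnorm(32 * 32), 32, 32)
  expect_lt(abs(spot_snr(bg, spot)), 1.5)
})

test_that("tracking mode relaxes the acceptance thresholds", {
  p0 <- detect_params()
  pt <- detect_params(tracking_mode = TRUE)
  expect_equal(pt$sigma_range, c(0.6, 3.0))
  expect_equal(pt$fit_residual_max, 1.5 * p0$fit_residual_max)
  expect_equal(pt$kernel_residual_max, p0$kernel_residual_max)
})
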