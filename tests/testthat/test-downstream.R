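test_that("stoichiometry inference is self-consistent on exact binomial histograms", {
  pm2 <- dbinom(0:2, 2, 0.5)
  h2 <- setNames(round(10000 * pm2), c("0", "1", "2"))
  s2 <- infer_stoichiometry(h2)
  expect_equal(s2$N_hat, 2L)
  expect_equal(s2$p_hat, 0.5, tolerance = 0.02)

  pm4 <- dbinom(0:4, 4, 0.6)
  h4 <- setNames(round(10000 * pm4), as.character(0:4))
  expect_equal(infer_stoichiometry(h4)$N_hat, 4L)

  # with the 0 bin observable, all mass in bin 1 forces N = 1, p -> 1
  h1 <- c("0" = 0, "1" = 500)
  s1 <- infer_stoichiometry(h1, include_zero = TRUE)
  expect_equal(s1$N_hat, 1L)
  expect_gt(s1$p_hat, 0.99)
  expect_true(s1$degenerate)
})

test_that("confidence is a normalized profile likelihood over candidate N", {
  h <- setNames(round(5000 * dbinom(0:3, 3, 0.4)), as.character(0:3))
  s <- infer_stoichiometry(h)
  expect_equal(sum(s$per_N$confidence), 1, tolerance = 1e-9)
  expect_true(all(s$per_N$confidence >= 0))
  expect_equal(s$per_N$N[which.max(s$per_N$confidence)], 3)
})

test_that("N is recovered from sampled histograms in the experimentally relevant regime", {
  set.seed(1)
  hits <- 0L; total <- 0L
  for (rep in 1:24) {
    N <- sample(2:4, 1)
    p <- runif(1, 0.4, 0.6)
    draws <- rbinom(1000, N, p)
    h <- table(factor(draws, levels = 0:5))
    names(h) <- c(as.character(0:4), "5+")
    s <- infer_stoichiometry(h)
    hits <- hits + (s$N_hat == N)
    total <- total + 1L
  }
  expect_gte(hits / total, 0.9)
})

test_that("histograms entirely above a candidate N rule that N out", {
  h <- c("0" = 0, "1" = 100, "2" = 200, "3" = 150)
  s <- infer_stoichiometry(h, N_range = 1:6)
  expect_true(all(!is.finite(s$per_N$logLik[s$per_N$N < 3])))
  expect_error(infer_stoichiometry(c("1" = 10)), "at least 30")
})

test_that("two-state FRET traces are segmented with correct state means and rates", {
  set.seed(2)
  p_sw <- 0.05  # per-frame switching: mean dwell 20 frames
  all_dwells <- list(`1` = numeric(0), `2` = numeric(0))
  mean_err <- numeric(0)
  for (rep in 1:150) {
    st <- integer(300); s <- sample(1:2, 1)
    for (t in 1:300) { if (runif(1) < p_sw) s <- 3L - s; st[t] <- s }
    E <- c(0.2, 0.8)[st]
    IA <- E * 200 + rnorm(300, 0, 12)
    ID <- (1 - E) * 200 + rnorm(300, 0, 12)
    fr <- detect_fret_states(ID, IA, n_states = 2)
    mean_err <- c(mean_err, abs(sort(fr$components$mean) - c(0.2, 0.8)))
    for (s2 in 1:2) all_dwells[[s2]] <- c(all_dwells[[s2]], fr$dwell_frames[[s2]])
  }
  expect_lt(max(tapply(mean_err, rep(1:2, length(mean_err) / 2), mean)), 0.05)
  # first-order exit rates from truncation-corrected mean dwells
  # (observed dwells are >= min_dwell = 4 frames); truth 0.5 / s
  rates <- vapply(all_dwells, function(d) 1 / ((mean(d) - 3) * 0.1), numeric(1))
  expect_equal(unname(rates), c(0.5, 0.5), tolerance = 0.2)
})

test_that("single-state traces yield one component and no transitions", {
  set.seed(3)
  IA <- 160 + rnorm(300, 0, 8); ID <- 40 + rnorm(300, 0, 8)
  fr <- detect_fret_states(ID, IA)
  expect_equal(fr$n_states, 1L)
  expect_equal(fr$n_transitions, 0L)
  expect_equal(fr$components$mean[1], 0.8, tolerance = 0.05)
})

test_that("dwells shorter than the minimum are absorbed into their neighbours", {
  set.seed(4)
  st <- c(rep(1L, 40), rep(2L, 3), rep(1L, 40), rep(2L, 30), rep(1L, 40))
  E <- c(0.2, 0.8)[st]
  IA <- E * 500 + rnorm(length(E), 0, 5)
  ID <- (1 - E) * 500 + rnorm(length(E), 0, 5)
  fr <- detect_fret_states(ID, IA, min_dwell = 4, n_states = 2)
  r <- rle(fr$states)
  expect_true(all(r$lengths >= 4))
  # the 3-frame excursion is gone; the genuine 30-frame dwell survives
  expect_equal(sum(r$values == which.max(fr$components$mean)), 1L)

  # frames with non-positive total intensity are masked
  fr2 <- detect_fret_states(c(-5, ID[-1]), c(2, IA[-1]), n_states = 2)
  expect_true(is.na(fr2$states[1]))
})
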