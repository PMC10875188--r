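test_that("the chromatic shift is linear with a fixed point at the origin", {
  tr <- chromatic_transform(F = 1, xc = 128, yc = 130, Sx = 900, Sy = 950)
  expect_equal(chromatic_shift(c(128, 130), tr), c(128, 130))
  # one scale length from the origin shifts by exactly one pixel
  expect_equal(chromatic_shift(c(128 + 900, 130), tr)[1], 128 + 900 + 1)
  # linear in F: the 561-channel factor scales the full shift by 0.35
  tr35 <- chromatic_transform(F = 0.35, xc = 128, yc = 130, Sx = 900, Sy = 950)
  d1 <- chromatic_shift(c(400, 300), tr) - c(400, 300)
  d35 <- chromatic_shift(c(400, 300), tr35) - c(400, 300)
  expect_equal(d35, 0.35 * d1)
  # linear in the distance from the origin
  d2 <- chromatic_shift(c(128 + 2 * (400 - 128), 130), tr)[1] - (128 + 2 * (400 - 128))
  expect_equal(d2, 2 * d1[1])
})

test_that("matching pairs identical lists exactly and respects the radius", {
  set.seed(1)
  A <- data.frame(x = runif(15, 50, 450), y = runif(15, 50, 450))
  ident <- chromatic_transform(F = 0)
  m <- match_spots(A, A, ident, radius = 2)
  expect_equal(nrow(m$pairs), 15L)
  expect_true(all(m$pairs$distance == 0))
  expect_equal(m$pairs$index_A, m$pairs$index_B)

  B <- data.frame(x = A$x + 5, y = A$y)  # farther than the radius
  expect_equal(nrow(match_spots(A, B, ident, radius = 2)$pairs), 0L)
})

test_that("the auto-solver recovers a planted transform from 20 jittered spots", {
  set.seed(2)
  A <- data.frame(x = runif(20, 140, 370), y = runif(20, 140, 370))
  F <- 1; xc <- 128; yc <- 130; Sx <- 900; Sy <- 950
  # B positions such that the forward shift maps them onto A (+0.1 px jitter)
  B <- data.frame(x = (A$x + F * xc / Sx) / (1 + F / Sx) + rnorm(20, 0, 0.07),
                  y = (A$y + F * yc / Sy) / (1 + F / Sy) + rnorm(20, 0, 0.07))
  sol <- solve_transform(A, B, F = 1, radius = 2)
  expect_true(sol$success)
  expect_equal(sol$n_pairs, 20L)
  expect_lt(sol$mean_distance, 0.3)
})

test_that("solving is invariant to spot ordering", {
  set.seed(3)
  A <- data.frame(x = runif(15, 150, 350), y = runif(15, 150, 350))
  B <- data.frame(x = A$x - 0.2, y = A$y + 0.3)
  s1 <- solve_transform(A, B, F = 1, radius = 2, grid_spacing = 32, n_s = 4)
  perm <- sample(15)
  s2 <- solve_transform(A[perm, ], B[rev(perm), ], F = 1, radius = 2,
                        grid_spacing = 32, n_s = 4)
  expect_equal(s1$n_pairs, s2$n_pairs)
  expect_equal(s1$mean_distance, s2$mean_distance, tolerance = 1e-6)
})

test_that("fewer than four colocalizable spots is a failure status", {
  set.seed(4)
  A <- data.frame(x = runif(3, 150, 350), y = runif(3, 150, 350))
  B <- data.frame(x = A$x + 0.1, y = A$y)
  sol <- solve_transform(A, B, F = 1, radius = 2, grid_spacing = 32, n_s = 4)
  expect_false(sol$success)
  expect_equal(sol$n_pairs, 0L)
})

test_that("unrelated sparse spot lists do not produce spurious solutions", {
  set.seed(5)
  for (i in 1:5) {
    A <- data.frame(x = runif(6, 140, 370), y = runif(6, 140, 370))
    B <- data.frame(x = runif(6, 140, 370), y = runif(6, 140, 370))
    sol <- solve_transform(A, B, F = 1, radius = 1, grid_spacing = 32, n_s = 4)
    expect_true(!sol$success || sol$n_pairs < 6L)
  }
})

test_that("spots outside the central analysis region are excluded from solving", {
  set.seed(6)
  # all spots in an outer corner: nothing to solve from
  A <- data.frame(x = runif(10, 5, 60), y = runif(10, 5, 60))
  B <- data.frame(x = A$x, y = A$y)
  sol <- solve_transform(A, B, F = 1, radius = 2, grid_spacing = 32, n_s = 4)
  expect_false(sol$success)
})
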