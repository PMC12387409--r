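# Moments here are unnormalized unit-disc integrals: a uniform image of
# value c has z00 = c * pi, and an ideal unit step through the centre has
# z11' = 2/3 in the continuum.

test_that("mask integrals match their closed-form disc values", {
  zm <- zernike_masks(9, 64)
  expect_equal(sum(zm$m00), pi, tolerance = 2e-3)
  expect_lt(abs(sum(zm$m11)), 1e-6)
  expect_lt(abs(sum(zm$m20)), 2e-3)
  # entries for cells wholly outside the disc vanish (the corners)
  expect_equal(zm$m00[1, 1], 0)
  expect_equal(zm$m20[1, 1], 0)
  expect_error(zernike_masks(8), "odd")
  expect_error(zernike_masks(9, 4), "subsampling")
})

test_that("masks carry the symmetries of their polynomials", {
  zm <- zernike_masks(9, 32)
  rot90 <- function(m) t(m)[, nrow(m):1]
  expect_equal(zm$m00, t(zm$m00))
  expect_equal(zm$m00, zm$m00[9:1, ])
  expect_equal(rot90(zm$m20), zm$m20, tolerance = 1e-6)
  # V11 = x + iy picks up a factor under a quarter turn of the grid
  expect_lt(max(Mod(rot90(zm$m11) + 1i * zm$m11)), 1e-6)
})

test_that("moments of uniform and ideal step images take known values", {
  zm <- zernike_masks(9, 64)
  u <- matrix(0.7, 9, 9)
  expect_equal(sum(u * zm$m00), 0.7 * pi, tolerance = 2e-3)
  expect_lt(abs(sum(u * zm$m11)), 1e-6)
  expect_lt(abs(sum(u * zm$m20)), 2e-3)
  # ideal vertical unit step through the centre: z11' = 2/3, z00 = pi/2
  W <- make_step_window(9, l = 0, theta = 0, h = 0, k = 1)
  z11 <- sum(W * zm$m11)
  expect_equal(Re(z11), 2 / 3, tolerance = 0.02)
  expect_lt(abs(Im(z11)), 1e-8)
  expect_lt(abs(sum(W * zm$m20)), 0.02)
  expect_equal(sum(W * zm$m00), pi / 2, tolerance = 0.01)
  # rotating the step leaves |z11| invariant and sets its argument
  W30 <- make_step_window(9, l = 0, theta = 30 * pi / 180, h = 0, k = 1)
  z11r <- sum(W30 * zm$m11)
  expect_equal(Mod(z11r), Mod(z11), tolerance = 0.02)
  expect_equal(Arg(z11r) * 180 / pi, 30, tolerance = 1)
})

test_that("compute_moments fields agree with direct windowed sums", {
  set.seed(21)
  img <- matrix(runif(20 * 20), 20, 20)
  zm <- zernike_masks(9, 32)
  mom <- compute_moments(img, zm)
  for (p in list(c(10, 10), c(7, 13))) {
    W <- img[(p[1] - 4):(p[1] + 4), (p[2] - 4):(p[2] + 4)]
    expect_equal(mom$z00[p[1], p[2]], sum(W * zm$m00), tolerance = 1e-10)
    expect_equal(mom$z11[p[1], p[2]], sum(W * zm$m11), tolerance = 1e-10)
    expect_equal(mom$z20[p[1], p[2]], sum(W * zm$m20), tolerance = 1e-10)
  }
  at <- compute_moments(img, zm, at = data.frame(row = 10, col = 10))
  expect_equal(at$z11, mom$z11[10, 10])
})

test_that("step parameters are recovered across the (l, theta, k, h) grid", {
  zm <- zernike_masks(9, 64)
  worst <- c(l = 0, k = 0, h = 0, th = 0)
  for (l in seq(-0.4, 0.4, by = 0.1)) {
    for (th in seq(0, 330, by = 30) * pi / 180) {
      for (k in c(0.5, 1)) {
        for (h in c(0, 0.2)) {
          W <- make_step_window(9, l, th, h, k)
          p <- edge_parameters(sum(W * zm$m00), sum(W * zm$m11),
                               sum(W * zm$m20))
          dth <- abs(atan2(sin(p$theta - th), cos(p$theta - th)))
          worst <- pmax(worst, c(abs(p$l - l), abs(p$k - k),
                                 abs(p$h - h), dth))
        }
      }
    }
  }
  expect_lt(worst[["l"]], 0.03)
  expect_lt(worst[["k"]], 0.05)
  expect_lt(worst[["h"]], 0.05)
  expect_lt(worst[["th"]], 2 * pi / 180)
})

test_that("parameter recovery is equivariant under quarter-turn rotation", {
  zm <- zernike_masks(9, 64)
  W <- make_step_window(9, l = 0.2, theta = 20 * pi / 180, h = 0.1, k = 0.8)
  rot90 <- function(m) t(m)[, nrow(m):1]
  p1 <- edge_parameters(sum(W * zm$m00), sum(W * zm$m11), sum(W * zm$m20))
  Wr <- rot90(W)
  p2 <- edge_parameters(sum(Wr * zm$m00), sum(Wr * zm$m11), sum(Wr * zm$m20))
  expect_equal(p2$l, p1$l, tolerance = 1e-3)
  expect_equal(p2$k, p1$k, tolerance = 1e-3)
  expect_equal(p2$h, p1$h, tolerance = 1e-3)
  dth <- atan2(sin(p2$theta - p1$theta), cos(p2$theta - p1$theta))
  expect_equal(abs(dth), pi / 2, tolerance = 1e-3)
})

test_that("degenerate moments are flagged instead of inverted", {
  p <- edge_parameters(0.5 * pi, 0 + 0i, 0)
  expect_true(p$flat)
  expect_true(is.na(p$l))
  # |l| > 1 before clamping marks a step-model violation
  p2 <- edge_parameters(1, 0.1 + 0i, 0.5)
  expect_true(p2$model_violation)
  expect_lte(abs(p2$l), 0.999)
  # z20 = 0 gives l = 0 exactly
  p3 <- edge_parameters(1, 0.4 + 0.3i, 0)
  expect_identical(p3$l, 0)
})

test_that("sub-pixel mapping follows the N*l/2 displacement rule", {
  expect_equal(subpixel_coordinates(10, 20, 0, 1.2, 9),
               data.frame(xs = 20, ys = 10))
  expect_equal(subpixel_coordinates(10, 20, 0.2, 0, 9),
               data.frame(xs = 20.9, ys = 10))
  expect_equal(subpixel_coordinates(10, 20, 0.2, pi / 2, 9),
               data.frame(xs = 20, ys = 10.9), tolerance = 1e-12)
})
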