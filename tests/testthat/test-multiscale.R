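test_that("single zero shift reduces accumulation to |convolution|", {
  set.seed(7)
  x <- matrix(runif(24 * 24), 24, 24)
  k <- mexican_hat_kernel(1.5, half_width = 4)
  s <- accumulate_shifted_responses(x, k, step = 1L)
  expect_equal(s$response, abs(convolve2(x, k)))
  expect_identical(s$offsets, 0L)
})

test_that("a constant image gives zero response for a zero-mean kernel", {
  k <- mexican_hat_kernel(2, half_width = 8)
  k <- k - mean(k)  # remove residual truncation mass
  x <- matrix(0.6, 30, 30)
  s <- accumulate_shifted_responses(x, k, step = 3L)
  expect_lt(max(abs(s$response)), 1e-12)
})

test_that("box-sum accumulation equals the brute-force shift loop", {
  set.seed(11)
  x <- matrix(runif(32 * 32), 32, 32)
  k <- matrix(rnorm(25), 5, 5)
  for (center in c(TRUE, FALSE)) {
    s <- accumulate_shifted_responses(x, k, step = 3L, center = center)
    expect_equal(s$response, oracle_accumulate(x, k, s$offsets),
                 tolerance = 1e-10)
  }
  expect_error(accumulate_shifted_responses(x, k, step = 0), "positive")
})

test_that("accumulation is translation-consistent in the interior", {
  set.seed(3)
  x <- matrix(runif(28 * 28), 28, 28)
  k <- mexican_hat_kernel(1.5, half_width = 4)
  s1 <- accumulate_shifted_responses(x, k, step = 2L)$response
  xs <- cbind(x[, 1], x[, -ncol(x)])  # shift content right by one column
  s2 <- accumulate_shifted_responses(xs, k, step = 2L)$response
  # interior columns of s2 equal s1 shifted by one
  expect_equal(s2[10:18, 10:18], s1[10:18, 9:17], tolerance = 1e-10)
})

test_that("scale fusion weights are a proper convex combination", {
  set.seed(5)
  a <- matrix(runif(100), 10, 10)
  f1 <- fuse_scales(list(a))
  expect_equal(f1$weights, 1.0)
  expect_equal(f1$total, a)
  f2 <- fuse_scales(list(a, a))
  expect_equal(f2$weights, c(0.5, 0.5), tolerance = 1e-9)
  b <- matrix(runif(100), 10, 10); c_ <- matrix(runif(100), 10, 10)
  f3 <- fuse_scales(list(a, b, c_))
  expect_true(all(f3$weights >= 0))
  expect_equal(sum(f3$weights), 1, tolerance = 1e-9)
  # weighted sum recomputed by hand with population stds
  stds <- sapply(list(a, b, c_), function(m) sqrt(mean((m - mean(m))^2)))
  w <- stds / sum(stds)
  expect_equal(f3$total, w[1] * a + w[2] * b + w[3] * c_, tolerance = 1e-12)
  expect_error(fuse_scales(list(matrix(1, 4, 4), matrix(2, 4, 4))),
               "degenerate")
  expect_error(fuse_scales(list(a, matrix(0, 3, 3))), "shape")
})

test_that("DoG enhancement annihilates constants and reproduces impulses", {
  d <- dog_kernel(1, 2, half_width = 8)
  flat <- enhance_with_dog(matrix(0.7, 40, 40), d)
  expect_lt(max(abs(flat[10:30, 10:30])), 1e-3 * 0.7)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  out <- enhance_with_dog(imp, d)
  expect_equal(out[(21 - 8):(21 + 8), (21 - 8):(21 + 8)], d,
               tolerance = 1e-10)
})

test_that("ring phantom structure dominates the DoG-enhanced response", {
  ph <- make_placido_phantom(width = 200, height = 200, center = c(100, 100),
                             ring_radii = seq(25, 85, by = 15), seed = 2)
  k <- enhanced_mhw_kernel(3)
  s <- accumulate_shifted_responses(ph$image, k, step = 6L)
  ef <- enhance_with_dog(fuse_scales(list(s))$total, dog_kernel(1, 2))
  g <- expand.grid(y = 1:200, x = 1:200)
  r <- sqrt((g$x - 100)^2 + (g$y - 100)^2)
  ring_zone <- r > 20 & r < 90
  background <- r > 100 | r < 12
  expect_gt(mean(abs(ef)[ring_zone]), 2 * mean(abs(ef)[background]))
})

test_that("coarse extraction keeps thin, clean candidate curves", {
  expect_warning(e0 <- extract_coarse_edges(matrix(0, 20, 20)), "no edge")
  expect_false(any(e0$mask))
  # component filter: 12-px segment survives, 3-px speck does not
  f <- matrix(0, 30, 30)
  f[10, 5:16] <- 1
  f[20, 3:5] <- 1
  ce <- extract_coarse_edges(f, min_component = 5, method = "magnitude")
  expect_true(any(ce$mask[10, ]))
  expect_false(any(ce$mask[20, ]))
})

test_that("the full front-end localizes the circle to a single thin ring", {
  img <- small_circle()
  ctl <- edge_detect_control()
  responses <- lapply(seq_along(ctl$scales), function(i)
    accumulate_shifted_responses(img,
                                 enhanced_mhw_kernel(ctl$scales[i]),
                                 step = ctl$step)$response)
  ef <- enhance_with_dog(fuse_scales(responses)$total,
                         dog_kernel(1, 2))
  ce <- extract_coarse_edges(ef, min_component = 5)
  pix <- which(ce$mask, arr.ind = TRUE)
  r <- sqrt((pix[, 2] - 80)^2 + (pix[, 1] - 80)^2)
  expect_true(all(abs(r - 50) <= 2))             # hugs the true circle
  expect_length(ce$component_sizes, 1L)          # one closed ring
  # thinned: no 2x2 block fully set
  m <- ce$mask * 1
  blocks <- m[-1, -1] + m[-1, -ncol(m)] + m[-nrow(m), -1] +
    m[-nrow(m), -ncol(m)]
  expect_true(all(blocks < 4))
})

test_that("multi-scale multi-position accumulation suppresses eyelash clutter", {
  # rings must be coarser than the eyelash strokes for the scale fusion to
  # separate them, as in clinical Placido images
  ph <- make_placido_phantom(ring_radii = seq(50, 170, by = 30),
                             ring_width = 10, n_eyelashes = 5L, seed = 4)
  extract_frac <- function(ce) {
    pix <- which(ce$mask)
    mean(ph$occluder_mask[pix])
  }
  # full front-end: three scales, step-6 shift block, zero-crossing edges
  responses <- lapply(c(3, 4, 6), function(s)
    accumulate_shifted_responses(ph$image, enhanced_mhw_kernel(s),
                                 step = 6L)$response)
  ef_full <- enhance_with_dog(fuse_scales(responses)$total, dog_kernel(1, 2))
  f_full <- extract_frac(extract_coarse_edges(ef_full, 5))
  # plain single-scale, single-position Mexican Hat front-end
  # (absolute-response magnitude thresholding, its native extraction)
  plain <- accumulate_shifted_responses(ph$image, mexican_hat_kernel(3),
                                        step = 1L)$response
  f_plain <- extract_frac(extract_coarse_edges(plain, 5, method = "magnitude"))
  expect_lt(f_full, f_plain)
})
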