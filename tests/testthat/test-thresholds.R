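test_that("gray-level threshold matches a scalar recomputation", {
  set.seed(31)
  z11 <- matrix(complex(real = rnorm(81), imaginary = rnorm(81)), 9, 9)
  z20 <- matrix(rnorm(81), 9, 9)
  gt <- gray_threshold_field(z11, z20)
  for (p in list(c(5, 5), c(4, 6), c(3, 3))) {
    expect_equal(gt$kt[p[1], p[2]], oracle_kt_at(z11, z20, p[1], p[2]),
                 tolerance = 1e-10)
  }
  expect_true(all(gt$var >= 0))
  expect_true(all(gt$sd >= 0))
})

test_that("degenerate statistics give a zero threshold", {
  z20 <- matrix(0.4, 8, 8)
  gt <- gray_threshold_field(matrix(0i, 8, 8), z20)
  expect_equal(max(abs(gt$var)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gt$kt)), 0, tolerance = 1e-12)
  expect_error(gray_threshold_field(matrix(0i, 3, 3), matrix(0, 4, 4)),
               "shape")
})

test_that("distance threshold reflects Hessian principal curvature", {
  # flat response: no curvature, baseline 2/N everywhere
  dt <- distance_threshold_field(matrix(0.3, 10, 10), size = 9)
  expect_equal(dt$lk, matrix(0, 10, 10))
  expect_equal(dt$lt, matrix(2 / 9, 10, 10))
  # response x^2/2 along columns: Hessian diag(1, 0) in the interior
  n <- 15
  f <- matrix(rep(((1:n) - 8)^2 / 2, each = n), n, n)
  dt2 <- distance_threshold_field(f, size = 9)
  expect_equal(dt2$lk[8, 8], 1)
  expect_equal(dt2$lt[8, 8], 2 / 9 + 0.2)
  # quadratic bowl: both curvatures 1
  g <- outer(((1:n) - 8)^2 / 2, ((1:n) - 8)^2 / 2, "+")
  dt3 <- distance_threshold_field(g, size = 9)
  expect_equal(dt3$lk[8, 8], 1)
  # negative curvature sign tightens instead of relaxing, floored at 0
  dt4 <- distance_threshold_field(f, size = 9, curvature_sign = -1)
  expect_equal(dt4$lt[8, 8], 2 / 9 - 0.2)
  expect_true(all(dt4$lt >= 0))
})

test_that("gating applies closed inequalities on k and l", {
  kt <- matrix(0.5, 5, 5)
  lt <- matrix(0.25, 5, 5)
  cand <- data.frame(row = c(3, 3, 3, 3), col = c(2, 3, 4, 5),
                     k = c(0.5, 0.49, 0.8, 0.8),
                     l = c(0.25, 0.1, 0.26, -0.25))
  g <- gate_candidates(cand, kt, lt)
  expect_identical(g$accepted, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(g$kt, rep(0.5, 4))
  expect_equal(g$lt, rep(0.25, 4))
})

test_that("gating agrees with scalar enumeration on random inputs", {
  set.seed(41)
  kt <- matrix(runif(100, 0, 0.5), 10, 10)
  lt <- matrix(runif(100, 0.1, 0.4), 10, 10)
  cand <- data.frame(row = sample(10, 30, TRUE), col = sample(10, 30, TRUE),
                     k = runif(30), l = runif(30, -0.6, 0.6))
  g <- gate_candidates(cand, kt, lt)
  for (i in seq_len(30)) {
    expect_identical(g$accepted[i],
                     cand$k[i] >= kt[cand$row[i], cand$col[i]] &&
                       abs(cand$l[i]) <= lt[cand$row[i], cand$col[i]])
  }
})

test_that("acceptance is monotone in the thresholds", {
  set.seed(43)
  kt <- matrix(runif(100, 0, 0.5), 10, 10)
  lt <- matrix(runif(100, 0.1, 0.4), 10, 10)
  cand <- data.frame(row = sample(10, 40, TRUE), col = sample(10, 40, TRUE),
                     k = runif(40), l = runif(40, -0.6, 0.6))
  base <- gate_candidates(cand, kt, lt)$accepted
  harder <- gate_candidates(cand, kt * 1.5, lt)$accepted
  softer <- gate_candidates(cand, kt, lt * 1.5)$accepted
  expect_true(all(harder <= base))   # raising kt never adds acceptances
  expect_true(all(softer >= base))   # raising lt never removes them
})

test_that("the gradient magnitude is invariant under image quarter turns", {
  set.seed(47)
  img <- matrix(runif(15 * 15), 15, 15)
  zm <- zernike_masks(9, 32)
  rot90 <- function(m) t(m)[, nrow(m):1]
  g1 <- Mod(compute_moments(img, zm)$z11)
  g2 <- Mod(compute_moments(rot90(img), zm)$z11)
  expect_equal(rot90(g1), g2, tolerance = 1e-6)
})
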