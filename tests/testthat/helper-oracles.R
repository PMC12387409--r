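# Independent oracles and shared fixtures for the test suite.

# Symmetric-reflection index oracle, written independently of the package
# implementation (explicit fold instead of modular arithmetic).
oracle_reflect <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# Direct 2-D convolution by explicit loops with reflective boundary.
oracle_conv2 <- function(x, k) {
  hw <- (nrow(k) - 1L) / 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    acc <- 0
    for (u in -hw:hw) for (v in -hw:hw) {
      acc <- acc + k[u + hw + 1L, v + hw + 1L] *
        x[oracle_reflect(i - u, nrow(x)), oracle_reflect(j - v, ncol(x))]
    }
    out[i, j] <- acc
  }
  out
}

# Brute-force shifted accumulation: explicit loop over the shift lattice.
oracle_accumulate <- function(x, k, offsets) {
  absC <- abs(oracle_conv2(x, k))
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    acc <- 0
    for (by in offsets) for (bx in offsets) {
      acc <- acc + absC[oracle_reflect(i + by, nrow(x)),
                        oracle_reflect(j + bx, ncol(x))]
    }
    out[i, j] <- acc
  }
  out
}

# Scalar recomputation of the gray-level threshold at one pixel.
oracle_kt_at <- function(z11, z20, i, j) {
  gk <- sqrt(Re(z11[i, j])^2 + Im(z11[i, j])^2)
  win <- Re(z20)[(i - 2):(i + 2), (j - 2):(j + 2)]
  mu <- sum(win) / 25
  va <- sum((win - mu)^2) / 24
  (gk^2 + sqrt(va)^2 + log(1 + va)) / 5
}

# Benchmark runs are expensive; compute once per session and cache.
.bench_cache <- new.env()
get_circle_benchmark <- function() {
  if (is.null(.bench_cache$b)) {
    .bench_cache$b <- circle_benchmark(eval_seeds = 1:10,
                                       noise_seeds = 101:105)
  }
  .bench_cache$b
}

# Small circle image shared by pipeline tests.
small_circle <- function(supersample = 4L) {
  make_binary_circle(width = 160L, height = 160L, center = c(80, 80),
                     radius = 50, supersample = supersample)
}
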