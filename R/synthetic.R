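## Synthetic test fixtures: the binary circle benchmark image, its noisy
## variant, Placido-ring phantoms with eyelash/spot interference, and
## analytic step-edge windows for moment oracles.  All generators are pure
## functions of their arguments (and seed); repeated calls are identical.

## evaluate a function of (x, y) pixel-centre coordinates on a grid
coord_grids <- function(width, height) {
  list(x = matrix(rep(seq_len(width), each = height), height, width),
       y = matrix(rep(seq_len(height), times = width), height, width))
}

#' Binary circle benchmark image
#'
#' A white disc on black background.  With `supersample = 1` (default) the
#' disc indicator is sampled at pixel centres: intensity 1 where
#' `(x - cx)^2 + (y - cy)^2 <= radius^2`, else 0 -- a hard binary image
#' whose boundary is aliased to the pixel grid.  With `supersample > 1`
#' each boundary pixel instead receives its area coverage fraction
#' (supersample^2 sub-samples), which renders the ideal circle with
#' sub-pixel fidelity the way an area-integrating sensor would.
#'
#' @param width,height image size in pixels (default 400 x 400).
#' @param center circle centre `(cx, cy)` in pixel units (default
#'   `(200, 200)`).
#' @param radius circle radius in pixels (default 150).
#' @param supersample sub-samples per pixel side for the boundary ring
#'   (1 = hard binary).
#' @return numeric matrix in \[0, 1\], indexed `[row = y, col = x]`.
#' @export
make_binary_circle <- function(width = 400L, height = 400L,
                               center = c(200, 200), radius = 150,
                               supersample = 1L) {
  cx <- center[1]; cy <- center[2]
  if (cx - radius < 0.5 || cy - radius < 0.5 ||
      cx + radius > width + 0.5 || cy + radius > height + 0.5)
    stop("circle does not fit inside the frame")
  g <- coord_grids(width, height)
  r2 <- (g$x - cx)^2 + (g$y - cy)^2
  img <- (r2 <= radius^2) * 1
  if (supersample > 1L) {
    band <- which(r2 > (radius - 1)^2 & r2 < (radius + 1)^2)
    off <- ((seq_len(supersample) - 0.5) / supersample - 0.5)
    ox <- matrix(off, supersample, supersample, byrow = TRUE)
    oy <- matrix(off, supersample, supersample)
    for (idx in band) {
      px <- g$x[idx]; py <- g$y[idx]
      img[idx] <- mean((px + ox - cx)^2 + (py + oy - cy)^2 <= radius^2)
    }
  }
  img
}

#' Add i.i.d. Gaussian noise to an image
#'
#' @param image numeric matrix on a \[0, 1\] scale.
#' @param sd noise standard deviation in intensity units.
#' @param seed optional integer; when given, the RNG state is saved and
#'   restored so the call is reproducible and side-effect free.
#' @param clip clip the result to \[0, 1\] (default `TRUE`).
#' @return noisy image matrix.
#' @export
add_gaussian_noise <- function(image, sd, seed = NULL, clip = TRUE) {
  if (sd < 0) stop("'sd' must be non-negative")
  if (sd == 0) return(image)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  out <- image + matrix(stats::rnorm(length(image), 0, sd),
                        nrow(image), ncol(image))
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Placido-ring phantom with eyelash and light-spot interference
#'
#' Concentric bright rings with Gaussian radial cross-sections on a dark
#' background, optionally occluded by dark eyelash-like polylines entering
#' from the top edge and bright specular spots.  Returns the image
#' together with its generating geometry and an occluder mask for
#' scoring.
#'
#' @param width,height image size (default 400 x 400).
#' @param center ring centre (default image centre).
#' @param ring_radii increasing ring radii in pixels (default 11 rings,
#'   15 px apart starting at 30).
#' @param ring_width ring full width in pixels (Gaussian sigma =
#'   `ring_width / 2`), default 4.
#' @param n_eyelashes,n_spots number of occluding polylines / bright
#'   spots.
#' @param seed integer fixing all randomness (default 1).
#' @return list with `image`, `center`, `ring_radii`, `occluder_mask`
#'   (logical matrix, `TRUE` on eyelash strokes) and `spot_centers`.
#' @export
make_placido_phantom <- function(width = 400L, height = 400L,
                                 center = c(width / 2, height / 2),
                                 ring_radii = seq(30, 180, by = 15),
                                 ring_width = 4,
                                 n_eyelashes = 0L, n_spots = 0L,
                                 seed = 1L) {
  if (is.unsorted(ring_radii, strictly = TRUE))
    stop("'ring_radii' must be strictly increasing")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- coord_grids(width, height)
  r <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  sig <- ring_width / 2
  img <- matrix(0.05, height, width)
  for (R in ring_radii) img <- img + 0.9 * exp(-(r - R)^2 / (2 * sig^2))
  img <- pmin(img, 1)
  occ <- matrix(FALSE, height, width)
  if (n_eyelashes > 0L) {
    for (e in seq_len(n_eyelashes)) {
      x0 <- stats::runif(1, 0.15 * width, 0.85 * width)
      len <- stats::runif(1, 0.3, 0.6) * height
      drift <- stats::runif(1, -0.4, 0.4)
      ys <- seq(1, len, by = 0.5)
      xs <- x0 + drift * ys + 3 * sin(ys / 25 + stats::runif(1, 0, 6))
      px <- round(xs); py <- round(ys)
      ok <- px >= 2 & px <= width - 1 & py >= 1 & py <= height
      for (dx in -1:1) {
        occ[cbind(py[ok], px[ok] + dx)] <- TRUE
      }
    }
    img[occ] <- 0.02
  }
  spot_centers <- NULL
  if (n_spots > 0L) {
    spot_centers <- cbind(x = stats::runif(n_spots, 0.2 * width, 0.8 * width),
                          y = stats::runif(n_spots, 0.2 * height, 0.8 * height))
    for (s in seq_len(n_spots)) {
      d2 <- (g$x - spot_centers[s, "x"])^2 + (g$y - spot_centers[s, "y"])^2
      img <- pmax(img, exp(-d2 / (2 * 3^2)))
    }
  }
  list(image = img, center = center, ring_radii = ring_radii,
       occluder_mask = occ, spot_centers = spot_centers)
}

#' Analytic step-edge window
#'
#' An `size` x `size` window sampling the continuous two-level step used
#' by the Zernike edge model: intensity `h` on one side of a straight line
#' and `h + k` on the other.  The line lies at signed distance
#' `l * size / 2` pixels from the window centre with normal angle `theta`
#' (the bright side is in the `+theta` direction).  Each pixel is averaged
#' over `supersample^2` sub-samples.
#'
#' @param size window side (odd).
#' @param l signed unit-disc distance of the edge (|l| < 1).
#' @param theta edge normal angle, radians.
#' @param h background intensity.
#' @param k step height.
#' @param supersample sub-samples per pixel side (default 16).
#' @return numeric `size` x `size` matrix.
#' @export
make_step_window <- function(size = 9L, l = 0, theta = 0, h = 0, k = 1,
                             supersample = 16L) {
  if (abs(l) >= 1) stop("|l| must be < 1")
  hw <- (size - 1) / 2
  off <- (seq_len(supersample) - 0.5) / supersample - 0.5
  ox <- matrix(off, supersample, supersample, byrow = TRUE)
  oy <- matrix(off, supersample, supersample)
  W <- matrix(0, size, size)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      X <- (j - 1 - hw) + ox
      Y <- (i - 1 - hw) + oy
      d <- (X * cos(theta) + Y * sin(theta)) / (size / 2)
      W[i, j] <- mean(ifelse(d >= l, h + k, h))
    }
  }
  W
}
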