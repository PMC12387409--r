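## Discrete kernels: Mexican Hat wavelet, radial Gaussian modulation, their
## product (the "enhanced" wavelet), and the difference-of-Gaussians filter.
## All kernels are square with odd side length so a centre pixel exists.

#' Squared-radius grid for a square kernel
#'
#' @param half_width integer half width; the kernel side is `2 * half_width + 1`.
#' @return matrix of x^2 + y^2 evaluated at integer offsets from the centre.
#' @keywords internal
kernel_r2 <- function(half_width) {
  d <- (-half_width):half_width
  outer(d^2, d^2, "+")
}

default_half_width <- function(sigma, target_radius = 0, bandwidth = 0) {
  ceiling(max(4 * sigma, target_radius + 3 * bandwidth))
}

#' Mexican Hat (Ricker) wavelet kernel
#'
#' Samples the 2-D Mexican Hat wavelet
#' \deqn{h(x, y) = \frac{1}{\sigma^2}\left(2 - \frac{x^2+y^2}{\sigma^2}\right)
#'   \exp\left(-\frac{x^2+y^2}{2\sigma^2}\right)}
#' at integer pixel offsets.  The kernel is the (sign-flipped, scaled)
#' Laplacian of a Gaussian: band-pass, isotropic, and zero at
#' \eqn{x^2+y^2 = 2\sigma^2}.
#'
#' @param sigma scale factor in pixels (> 0).
#' @param half_width kernel half width in pixels; defaults to
#'   `ceiling(4 * sigma)`, which captures essentially all of the support.
#' @return a `(2*half_width+1)` square numeric matrix.
#' @examples
#' k <- mexican_hat_kernel(2)
#' k[ceiling(nrow(k) / 2), ceiling(ncol(k) / 2)]  # centre value 2 / sigma^2
#' @export
mexican_hat_kernel <- function(sigma, half_width = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  if (is.null(half_width)) half_width <- default_half_width(sigma)
  r2 <- kernel_r2(half_width)
  (1 / sigma^2) * (2 - r2 / sigma^2) * exp(-r2 / (2 * sigma^2))
}

#' Radial Gaussian enhancement kernel
#'
#' An annular weight \eqn{g(x, y) = \exp(-(r - R)^2 / \delta^2)} with
#' \eqn{r = \sqrt{x^2 + y^2}}: maximal (1) on the circle \eqn{r = R} and
#' decaying with radial distance from that circle.  Multiplying a wavelet by
#' this term concentrates its response on an annulus, which is what lets the
#' front-end amplify ring structure away from the kernel centre.
#'
#' The radial deviation is measured as distance-from-centre minus target
#' radius (`radial_term = "r"`).  The literal squared-radius reading
#' (`"r2"`, \eqn{(x^2+y^2-R)^2/\delta^2}) is retained for comparison but is
#' dimensionally inconsistent and not the default.
#'
#' @param target_radius annulus centre radius R in pixels (>= 0).
#' @param bandwidth radial selection bandwidth \eqn{\delta} in pixels (> 0).
#' @param half_width kernel half width in pixels.
#' @param radial_term `"r"` (default) or `"r2"`, see Details.
#' @return a square numeric matrix with values in (0, 1].
#' @export
radial_enhancement_kernel <- function(target_radius, bandwidth, half_width,
                                      radial_term = c("r", "r2")) {
  radial_term <- match.arg(radial_term)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("'bandwidth' must be a single positive number")
  if (!is.numeric(target_radius) || length(target_radius) != 1L || target_radius < 0)
    stop("'target_radius' must be a single non-negative number")
  r2 <- kernel_r2(half_width)
  dev <- if (radial_term == "r") sqrt(r2) - target_radius else r2 - target_radius
  exp(-dev^2 / bandwidth^2)
}

#' Radially modulated (enhanced) Mexican Hat kernel
#'
#' Elementwise product of [mexican_hat_kernel()] and
#' [radial_enhancement_kernel()] on a common grid.  The default half width,
#' `ceiling(max(4 * sigma, target_radius + 3 * bandwidth))`, covers the
#' support of both factors.
#'
#' @inheritParams mexican_hat_kernel
#' @inheritParams radial_enhancement_kernel
#' @param target_radius annulus radius R in pixels; defaults to `sigma`.
#' @param bandwidth radial bandwidth in pixels; defaults to `sigma`.
#' @return a square numeric matrix.
#' @export
enhanced_mhw_kernel <- function(sigma, target_radius = sigma, bandwidth = sigma,
                                half_width = NULL, radial_term = c("r", "r2")) {
  radial_term <- match.arg(radial_term)
  if (is.null(half_width))
    half_width <- default_half_width(sigma, target_radius, bandwidth)
  mexican_hat_kernel(sigma, half_width) *
    radial_enhancement_kernel(target_radius, bandwidth, half_width, radial_term)
}

#' Difference-of-Gaussians kernel
#'
#' \deqn{DoG(x,y) = \frac{1}{2\pi\sigma_1^2} e^{-r^2/2\sigma_1^2}
#'              - \frac{1}{2\pi\sigma_2^2} e^{-r^2/2\sigma_2^2}, \quad
#'              \sigma_1 < \sigma_2.}
#' Both Gaussians carry unit mass, so the kernel sums to approximately zero
#' over a sufficiently wide support and acts as a band-pass filter that
#' separates bright rings from the background.
#'
#' @param sigma1 inner (narrow) Gaussian standard deviation in pixels.
#' @param sigma2 outer (wide) Gaussian standard deviation in pixels;
#'   must exceed `sigma1`.
#' @param half_width kernel half width; defaults to `ceiling(4 * sigma2)`.
#' @return a square numeric matrix.
#' @export
dog_kernel <- function(sigma1, sigma2, half_width = NULL) {
  if (!is.numeric(sigma1) || !is.numeric(sigma2) ||
      length(sigma1) != 1L || length(sigma2) != 1L ||
      sigma1 <= 0 || sigma2 <= sigma1)
    stop("DoG parameters must satisfy 0 < sigma1 < sigma2")
  if (is.null(half_width)) half_width <- ceiling(4 * sigma2)
  r2 <- kernel_r2(half_width)
  (1 / (2 * pi * sigma1^2)) * exp(-r2 / (2 * sigma1^2)) -
    (1 / (2 * pi * sigma2^2)) * exp(-r2 / (2 * sigma2^2))
}

#' Isotropic Gaussian smoothing kernel (unit mass)
#' @keywords internal
gaussian_kernel <- function(sigma, half_width = ceiling(3 * sigma)) {
  k <- exp(-kernel_r2(half_width) / (2 * sigma^2))
  k / sum(k)
}

#' Write kernels as plain-text matrices
#'
#' One whitespace-delimited text file per kernel, for external inspection.
#'
#' @param kernels named list of numeric matrices.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
dump_kernels <- function(kernels, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(kernels), function(nm) {
    p <- file.path(dir, paste0(nm, ".txt"))
    utils::write.table(kernels[[nm]], p, row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
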