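## Zernike moment templates and the ideal step-edge inversion.
##
## The N x N template square is inscribed in the unit disc (cell side 2/N).
## Each mask entry is the integral of the polynomial over the cell's
## intersection with the disc, evaluated by midpoint subsampling; samples
## outside the disc contribute zero, which realizes the pixel-area weight.
##
## Moments are *unnormalized* disc integrals,
##   z_nm = sum(window * mask_nm)  ~  integral I(x, y) V_nm(x, y) dA,
## because the step-edge inversion below (l = z20 / z11', k = 3 z11' / 2 ...)
## is exact in that convention: for an ideal unit step at signed offset l,
## brute-force integration gives A20 / A11 = l identically, whereas the
## order-dependent prefactors (n+1)/pi would distort the ratio by 3/2.
## The angular template is V11 = rho * exp(i * theta) = x + i y (y = row
## axis, pointing down), so Arg(z11) is the edge normal pointing from the
## dark to the bright side.

.mask_cache <- new.env(parent = emptyenv())

#' Build Zernike moment templates
#'
#' Constructs the order (0,0), (1,1) and (2,0) templates on an `size` x
#' `size` grid by midpoint-subsampled integration over the unit disc.
#'
#' @param size odd template side length N (default 9).
#' @param subsampling sub-samples per cell side used for the disc
#'   integration (default 64; the disc-area check `sum(m00) = pi` is then
#'   accurate to well under 1e-3).
#' @return object of class `"zernike_masks"`: list with real matrices `m00`
#'   and `m20`, complex matrix `m11`, and the generating parameters.
#' @examples
#' zm <- zernike_masks(9)
#' sum(zm$m00) - pi           # ~ 0: disc area
#' abs(sum(zm$m11))           # ~ 0: odd integrand
#' @export
zernike_masks <- function(size = 9L, subsampling = 64L) {
  if (size %% 2L == 0L || size < 3L) stop("'size' must be an odd integer >= 3")
  if (subsampling < 8L) stop("'subsampling' must be at least 8")
  key <- paste(size, subsampling, sep = "_")
  if (!is.null(.mask_cache[[key]])) return(.mask_cache[[key]])
  hw <- (size - 1L) / 2
  cell <- 2 / size
  off <- ((seq_len(subsampling) - 0.5) / subsampling - 0.5) * cell
  m00 <- matrix(0, size, size)
  m11 <- matrix(0i, size, size)
  m20 <- matrix(0, size, size)
  dA <- (cell / subsampling)^2
  for (i in seq_len(size)) {
    cy <- (i - 1L - hw) * cell
    ys <- cy + off
    for (j in seq_len(size)) {
      cx <- (j - 1L - hw) * cell
      xs <- cx + off
      X <- matrix(xs, subsampling, subsampling, byrow = TRUE)
      Y <- matrix(ys, subsampling, subsampling)
      rho2 <- X^2 + Y^2
      inside <- rho2 <= 1
      m00[i, j] <- sum(inside) * dA
      m11[i, j] <- sum(X[inside] + 1i * Y[inside]) * dA
      m20[i, j] <- sum(2 * rho2[inside] - 1) * dA
    }
  }
  out <- structure(list(m00 = m00, m11 = m11, m20 = m20,
                        size = size, subsampling = subsampling),
                   class = "zernike_masks")
  .mask_cache[[key]] <- out
  out
}

#' @export
print.zernike_masks <- function(x, ...) {
  cat(sprintf("Zernike templates %dx%d (subsampling %d): sum(m00) = %.6f\n",
              x$size, x$size, x$subsampling, sum(x$m00)))
  invisible(x)
}

#' Write Zernike masks as plain-text matrices
#' @param masks a [zernike_masks()] object.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
dump_masks <- function(masks, dir) {
  dump_kernels(list(m00 = masks$m00,
                    m11_re = Re(masks$m11), m11_im = Im(masks$m11),
                    m20 = masks$m20), dir)
}

#' Compute Zernike moments of an image
#'
#' Correlates the image with the three templates.  With `at = NULL` full
#' moment fields are returned (one value per pixel, windows at the borders
#' use reflective padding); otherwise moments are returned only at the
#' given integer pixel positions.
#'
#' Moments are unnormalized disc integrals (see the module notes): a
#' uniform image of value `c` has `z00 = c * pi`, `z11 = 0`, `z20 = 0`.
#'
#' @param image numeric matrix.
#' @param masks a [zernike_masks()] object.
#' @param at optional integer matrix/data.frame with columns `row`, `col`.
#' @return with `at = NULL`, list of fields `z00` (real), `z11` (complex),
#'   `z20` (real); otherwise a data.frame with columns `row`, `col`, `z00`,
#'   `z11` (complex), `z20`.
#' @export
compute_moments <- function(image, masks = zernike_masks(), at = NULL) {
  z00 <- xcorr2(image, masks$m00)
  z11 <- xcorr2(image, Re(masks$m11)) + 1i * xcorr2(image, Im(masks$m11))
  z20 <- xcorr2(image, masks$m20)
  if (is.null(at)) return(list(z00 = z00, z11 = z11, z20 = z20))
  at <- as.matrix(at[, c("row", "col")])
  idx <- cbind(at[, 1], at[, 2])
  data.frame(row = at[, 1], col = at[, 2],
             z00 = z00[idx], z11 = z11[idx], z20 = z20[idx])
}

#' Recover ideal step-edge parameters from Zernike moments
#'
#' Inverts the two-level step model: a straight edge at signed unit-disc
#' distance `l` from the window centre, normal angle `theta`, background
#' level `h` on one side and `h + k` on the other.
#'
#' \deqn{\theta = \arg z_{11}, \quad z_{11}' = |z_{11}|, \quad
#'       l = z_{20} / z_{11}', \quad
#'       k = 3 z_{11}' / (2 (1 - l^2)^{3/2}),}
#' \deqn{h = (z_{00} - k\pi/2 + k \sin^{-1} l + k l \sqrt{1 - l^2}) / \pi.}
#'
#' `l` is clamped to \[-0.999, 0.999\] before the `(1 - l^2)^{3/2}` power;
#' `model_violation` flags candidates whose pre-clamp `|l|` exceeded 1.
#' Windows with `|z11|` below `tol` carry no gradient; their parameters are
#' returned as `NA` with `flat = TRUE`.
#'
#' @param z00,z20 real moments (vectors).
#' @param z11 complex moment (vector).
#' @param tol flat-region cutoff on `|z11|` (default 1e-12).
#' @return data.frame with columns `l`, `k`, `h`, `theta`, `flat`,
#'   `model_violation`.
#' @export
edge_parameters <- function(z00, z11, z20, tol = 1e-12) {
  z11p <- Mod(z11)
  theta <- Arg(z11)
  flat <- z11p < tol
  l_raw <- ifelse(flat, NA_real_, Re(z20) / z11p)
  violation <- !is.na(l_raw) & abs(l_raw) > 1
  l <- pmin(pmax(l_raw, -0.999), 0.999)
  k <- 3 * z11p / (2 * (1 - l^2)^1.5)
  h <- (Re(z00) - k * pi / 2 + k * asin(l) + k * l * sqrt(1 - l^2)) / pi
  data.frame(l = l, k = ifelse(flat, NA_real_, k),
             h = ifelse(flat, NA_real_, h),
             theta = ifelse(flat, NA_real_, theta),
             flat = flat, model_violation = violation)
}

#' Map a pixel and its step-edge parameters to sub-pixel coordinates
#'
#' \deqn{x_s = x + \frac{N l}{2}\cos\theta, \qquad
#'       y_s = y + \frac{N l}{2}\sin\theta}
#' where `x` is the column index and `y` the row index of the candidate
#' pixel and `N` the template size.
#'
#' @param row,col integer pixel position (vectors).
#' @param l signed unit-disc distance.
#' @param theta edge normal angle in radians.
#' @param size template side N.
#' @return data.frame with columns `xs`, `ys`.
#' @export
subpixel_coordinates <- function(row, col, l, theta, size = 9L) {
  data.frame(xs = col + (size * l / 2) * cos(theta),
             ys = row + (size * l / 2) * sin(theta))
}
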