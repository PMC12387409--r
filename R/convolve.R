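## 2-D filtering helpers.  All spatial filtering in the package goes through
## these wrappers so the boundary convention (symmetric reflection) is applied
## uniformly.  The FFT product itself is EBImage::filter2.

## Index vector that extends 1:n by `pad` samples of symmetric reflection
## (edge sample repeated: ..., 2, 1 | 1, 2, ..., n | n, n-1, ...), folding as
## often as needed for pads wider than the image.
reflect_index <- function(n, pad) {
  idx <- seq.int(1 - pad, n + pad)
  period <- 2L * n
  m <- ((idx - 1L) %% period + period) %% period  # 0 .. 2n-1
  ifelse(m < n, m + 1L, period - m)
}

#' Pad a matrix by symmetric reflection
#' @keywords internal
pad_reflect <- function(x, pad) {
  x[reflect_index(nrow(x), pad), reflect_index(ncol(x), pad), drop = FALSE]
}

#' 2-D convolution with reflective boundary
#'
#' Convolves `x` with a square odd-sided `kernel`, padding `x` by symmetric
#' reflection so the output has the same dimensions and no wrap-around
#' artefacts.
#'
#' @param x numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return numeric matrix with `dim(x)`.
#' @export
convolve2 <- function(x, kernel) {
  if (nrow(kernel) %% 2L == 0L || ncol(kernel) %% 2L == 0L)
    stop("'kernel' must have odd dimensions")
  pad <- max((dim(kernel) - 1L) %/% 2L) + 1L
  xp <- pad_reflect(x, pad)
  y <- EBImage::filter2(xp, kernel, boundary = "circular")
  y[(pad + 1L):(pad + nrow(x)), (pad + 1L):(pad + ncol(x)), drop = FALSE]
}

## Cross-correlation = convolution with the 180-degree rotated kernel.
## Used for template matching (Zernike masks, local statistics windows),
## where the mask must not be flipped.
xcorr2 <- function(x, kernel) {
  convolve2(x, kernel[nrow(kernel):1, ncol(kernel):1, drop = FALSE])
}

## Shift a matrix by (dr, dc) with symmetric reflection at the borders:
## result[i, j] = x[i + dr, j + dc] (reflected out-of-range).
shift_reflect <- function(x, dr, dc) {
  pad <- max(abs(dr), abs(dc))
  if (pad == 0L) return(x)
  xp <- pad_reflect(x, pad)
  xp[(pad + 1L + dr):(pad + dr + nrow(x)),
     (pad + 1L + dc):(pad + dc + ncol(x)), drop = FALSE]
}

## min-max normalization to [0, 1]; constant input maps to all zeros.
normalize01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

## Otsu's threshold of a numeric vector/matrix (values any finite range).
## Delegates to EBImage's histogram-based implementation on the normalized
## values; returns the threshold on the original scale.
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) return(rng[1])
  img <- EBImage::Image(matrix(v, nrow = 1L))
  th <- EBImage::otsu(img, range = rng, levels = levels)
  as.numeric(th)
}
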