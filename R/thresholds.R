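## Adaptive acceptance thresholds for Zernike step-edge candidates.
##
## A candidate pixel is a genuine edge point when its step height k reaches
## the local gray-level threshold kt and its unit-disc offset |l| stays
## within the distance threshold lt.  Both thresholds adapt to the local
## image structure: kt to gradient/variance statistics of the moment
## fields, lt to Hessian principal curvature of the filtered response.

#' Gray-level threshold field from local gradient and variance
#'
#' Per pixel, with the moment fields of the image:
#' \deqn{G_k = |z_{11}|, \quad
#'       \mu_k = \frac{1}{25}\sum_{5\times 5} z_{20}, \quad
#'       \upsilon_k = \frac{1}{24}\sum_{5\times 5} (z_{20} - \mu_k)^2, \quad
#'       \sigma_k = \sqrt{\upsilon_k}}
#' \deqn{k_t = (G_k^2 + \sigma_k^2 + \ln(1 + \upsilon_k)) / 5.}
#' The 5x5 window statistics use mean divisor 25 and unbiased variance
#' divisor 24.  High local gradient or dispersion raises the bar a
#' candidate's step height must clear, suppressing noise-driven candidates.
#'
#' @param z11_field complex moment field.
#' @param z20_field real moment field (same shape).
#' @return list of same-shaped fields: `gk`, `mu`, `var`, `sd`, `kt`.
#' @export
gray_threshold_field <- function(z11_field, z20_field) {
  if (!identical(dim(z11_field), dim(z20_field)))
    stop("moment fields must share their shape")
  gk <- Mod(z11_field)
  z20 <- Re(z20_field)
  ones5 <- matrix(1, 5, 5)
  mu <- xcorr2(z20, ones5) / 25
  ssq <- xcorr2(z20^2, ones5)
  va <- pmax((ssq - 25 * mu^2) / 24, 0)
  sd_ <- sqrt(va)
  kt <- (gk^2 + sd_^2 + log1p(va)) / 5
  list(gk = gk, mu = mu, var = va, sd = sd_, kt = kt)
}

#' Distance threshold field from Hessian principal curvature
#'
#' The Hessian of the (\[0, 1\]-normalized) response is built from central
#' second differences; its eigenvalues \eqn{\lambda_1, \lambda_2} give the
#' principal curvatures and
#' \deqn{l_k = \max(|\lambda_1|, |\lambda_2|), \qquad
#'       l_t = 2/N + s \cdot 0.2\, l_k.}
#' With the default sign `s = +1` (as the formula is printed) curved
#' regions receive a *larger* tolerance; `curvature_sign = -1` implements
#' the alternative reading in which high curvature tightens the threshold
#' (then floored at 0).
#'
#' @param response numeric matrix, normalized to \[0, 1\].
#' @param size Zernike template side N (the `2/N` baseline).
#' @param curvature_sign `+1` (default) or `-1`.
#' @return list of fields `lk` and `lt`.
#' @export
distance_threshold_field <- function(response, size = 9L, curvature_sign = 1) {
  f <- response
  fxx <- shift_reflect(f, 0L, 1L) - 2 * f + shift_reflect(f, 0L, -1L)
  fyy <- shift_reflect(f, 1L, 0L) - 2 * f + shift_reflect(f, -1L, 0L)
  fxy <- (shift_reflect(f, 1L, 1L) - shift_reflect(f, 1L, -1L) -
            shift_reflect(f, -1L, 1L) + shift_reflect(f, -1L, -1L)) / 4
  half_tr <- (fxx + fyy) / 2
  disc <- sqrt(((fxx - fyy) / 2)^2 + fxy^2)
  lk <- pmax(abs(half_tr + disc), abs(half_tr - disc))
  lt <- 2 / size + sign(curvature_sign) * 0.2 * lk
  if (curvature_sign < 0) lt <- pmax(lt, 0)
  list(lk = lk, lt = lt)
}

#' Gate step-edge candidates with the two adaptive thresholds
#'
#' A candidate is accepted when `k >= kt` and `|l| <= lt` at its pixel
#' (closed inequalities), and it is neither flat nor a step-model
#' violation.  Rejected candidates are retained with `accepted = FALSE`
#' for diagnostics.
#'
#' @param candidates data.frame with columns `row`, `col`, `k`, `l`
#'   (and optionally the flags from [edge_parameters()]).
#' @param kt_field,lt_field threshold fields on the candidate grid.
#' @return `candidates` with added columns `kt`, `lt`, `accepted`.
#' @export
gate_candidates <- function(candidates, kt_field, lt_field) {
  idx <- cbind(candidates$row, candidates$col)
  kt <- kt_field[idx]
  lt <- lt_field[idx]
  ok <- !is.na(candidates$k) & !is.na(candidates$l) &
    candidates$k >= kt & abs(candidates$l) <= lt
  if (!is.null(candidates$flat)) ok <- ok & !candidates$flat
  if (!is.null(candidates$model_violation)) ok <- ok & !candidates$model_violation
  candidates$kt <- kt
  candidates$lt <- lt
  candidates$accepted <- ok
  candidates
}
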