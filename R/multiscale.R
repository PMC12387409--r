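## Multi-scale, multi-position front-end: accumulate shifted convolution
## responses per scale, fuse scales with dispersion-derived weights, sharpen
## with a DoG, and extract pixel-level (coarse) edge candidates.

#' Accumulate shifted convolution responses at one scale
#'
#' Convolves the image with a wavelet kernel and sums the absolute response
#' over a lattice of integer translations:
#' \deqn{S_\sigma(x, y) = \sum_{b_x}\sum_{b_y} |(I * h_\sigma)(x + b_x, y + b_y)|}
#' which is a box sum of the absolute convolution response over the shift
#' lattice.  Summing positions suppresses isolated interference (eyelash
#' fragments, specular spots) relative to extended ring structure.
#'
#' By default the lattice is the centred block
#' `{0, ..., step-1} - floor(step/2)` in both directions; a forward block
#' `{0, ..., step-1}` (set `center = FALSE`) displaces the accumulated field
#' by half the step diagonally.  Boundaries are handled by symmetric
#' reflection, consistently with [convolve2()].
#'
#' @param image numeric matrix on a \[0, 1\] intensity scale.
#' @param kernel wavelet kernel, e.g. from [enhanced_mhw_kernel()].
#' @param step positive integer: side of the shift block.
#' @param offsets optional integer vector overriding the shift lattice
#'   (used for both directions); when supplied, `step`/`center` are ignored.
#' @param center logical: centre the shift block (default `TRUE`).
#' @return list with elements `response` (non-negative matrix, same shape as
#'   `image`) and `offsets` (the lattice used).
#' @export
accumulate_shifted_responses <- function(image, kernel, step = 6L,
                                         offsets = NULL, center = TRUE) {
  if (is.null(offsets)) {
    if (!is.numeric(step) || length(step) != 1L || step < 1)
      stop("'step' must be a positive integer")
    step <- as.integer(step)
    offsets <- 0L:(step - 1L)
    if (center) offsets <- offsets - step %/% 2L
  }
  offsets <- as.integer(offsets)
  absC <- abs(convolve2(image, kernel))
  S <- matrix(0, nrow(image), ncol(image))
  for (by in offsets) for (bx in offsets) {
    S <- S + shift_reflect(absC, by, bx)
  }
  list(response = S, offsets = offsets)
}

#' Fuse per-scale responses with dispersion-derived weights
#'
#' Each scale's accumulated response is weighted by its standard deviation
#' over all pixels, normalized so the weights sum to one:
#' \deqn{M_\sigma = \mathrm{std}(S_\sigma) / \sum_{\sigma'} \mathrm{std}(S_{\sigma'}),
#'       \qquad E = \sum_\sigma M_\sigma S_\sigma.}
#' Scales whose response varies strongly (i.e. carry edge contrast)
#' dominate; weak, flat responses are suppressed.
#'
#' @param responses list of same-shaped non-negative matrices (the
#'   `response` element of [accumulate_shifted_responses()] output).
#' @return list with `total` (fused response matrix) and `weights`
#'   (numeric vector summing to 1).
#' @export
fuse_scales <- function(responses) {
  if (length(responses) < 1L) stop("need at least one scale response")
  responses <- lapply(responses, function(r) if (is.list(r)) r$response else r)
  d <- dim(responses[[1]])
  if (!all(vapply(responses, function(r) identical(dim(r), d), logical(1))))
    stop("all responses must have the same shape")
  ## population standard deviation over all pixels of each field
  stds <- vapply(responses, function(r) {
    m <- mean(r); sqrt(mean((r - m)^2))
  }, numeric(1))
  if (sum(stds) <= 0) stop("degenerate input: every scale response is constant")
  w <- stds / sum(stds)
  total <- matrix(0, d[1], d[2])
  for (i in seq_along(responses)) total <- total + w[i] * responses[[i]]
  list(total = total, weights = w)
}

#' Sharpen the fused response with a difference-of-Gaussians filter
#'
#' Convolves the fused total response with a DoG kernel (reflective
#' boundary).  The DoG removes the smooth baseline and accentuates the
#' transition between bright and dark rings; the output is signed.
#'
#' @param total fused response matrix from [fuse_scales()].
#' @param dog DoG kernel from [dog_kernel()].
#' @return signed numeric matrix, same shape as `total`.
#' @export
enhance_with_dog <- function(total, dog) {
  convolve2(total, dog)
}

#' Extract coarse (pixel-level) edge candidates
#'
#' Two extraction rules are available for the signed, DoG-sharpened response:
#'
#' * `"zero_crossing"` (default): an edge passes between pixels where the
#'   response changes sign; the pixel on the smaller-magnitude side of each
#'   sign change is marked, with the jump magnitude across the crossing as
#'   its strength.  Weak crossings (flat-region ripple) are removed by
#'   Otsu's threshold on the strengths.  This is the classical reading of a
#'   band-pass (DoG/LoG) response, and it localizes a smoothed step at its
#'   inflection.
#' * `"magnitude"`: Otsu's threshold on the normalized absolute response
#'   followed by thinning.  On step-like structure the absolute DoG response
#'   peaks on both flanks of the edge, so this rule tends to produce flank
#'   ridges rather than the edge itself; it is retained for comparison.
#'
#' Either mask is thinned to 1-pixel curves (Zhang-Suen) and connected
#' components (8-connectivity) smaller than `min_component` pixels are
#' dropped.
#'
#' @param enhanced signed response matrix from [enhance_with_dog()].
#' @param min_component minimum component size in pixels (default 5).
#' @param method `"zero_crossing"` or `"magnitude"`.
#' @return object of class `"coarse_edges"`: list with `mask` (logical
#'   matrix), `component_sizes` (integer vector) and `strength` (numeric
#'   matrix of crossing strengths; zero where not a candidate).
#' @export
extract_coarse_edges <- function(enhanced, min_component = 5L,
                                 method = c("zero_crossing", "magnitude")) {
  method <- match.arg(method)
  if (!all(is.finite(enhanced))) stop("'enhanced' must be finite")
  if (method == "zero_crossing") {
    strength <- zero_crossing_strength(enhanced)
    vals <- strength[strength > 0]
    if (length(vals) == 0L) {
      warning("no edge candidates found")
      return(new_coarse_edges(matrix(FALSE, nrow(enhanced), ncol(enhanced)),
                              integer(0), strength))
    }
    th <- otsu_threshold(vals)
    mask <- strength > th
  } else {
    a <- normalize01(abs(enhanced))
    if (max(a) <= 0) {
      warning("no edge candidates found")
      return(new_coarse_edges(matrix(FALSE, nrow(enhanced), ncol(enhanced)),
                              integer(0), a))
    }
    th <- otsu_threshold(a)
    mask <- a > th
    strength <- a * mask
  }
  mask <- thin_mask(mask)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component)
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask
  if (!any(mask)) warning("no edge candidates survive component filtering")
  new_coarse_edges(mask, sizes[keep], strength * mask)
}

new_coarse_edges <- function(mask, component_sizes, strength) {
  structure(list(mask = mask, component_sizes = component_sizes,
                 strength = strength),
            class = "coarse_edges")
}

#' @export
print.coarse_edges <- function(x, ...) {
  cat("Coarse edge mask:", sum(x$mask), "candidate pixels in",
      length(x$component_sizes), "components\n")
  invisible(x)
}

## Per-pixel zero-crossing strength of a signed field: for each 4-neighbour
## pair straddling zero, the jump |a - b| (on the max-|.|-normalized field)
## is credited to the smaller-magnitude pixel; a pixel's strength is the
## largest jump it participates in.
zero_crossing_strength <- function(f) {
  m <- max(abs(f))
  if (m <= 0) return(f * 0)
  f <- f / m
  nr <- nrow(f); nc <- ncol(f)
  strength <- matrix(0, nr, nc)
  credit <- function(a, b, ia, ib) {
    ## a, b: values of the pair; ia, ib: index matrices into `strength`
    cross <- (a * b) < 0
    jump <- abs(a - b)
    toA <- cross & (abs(a) <= abs(b))
    toB <- cross & !toA
    strength[ia[toA]] <<- pmax(strength[ia[toA]], jump[toA])
    strength[ib[toB]] <<- pmax(strength[ib[toB]], jump[toB])
  }
  idx <- matrix(seq_along(f), nr, nc)
  ## horizontal pairs (j, j+1)
  credit(f[, -nc, drop = FALSE], f[, -1, drop = FALSE],
         idx[, -nc, drop = FALSE], idx[, -1, drop = FALSE])
  ## vertical pairs (i, i+1)
  credit(f[-nr, , drop = FALSE], f[-1, , drop = FALSE],
         idx[-nr, , drop = FALSE], idx[-1, , drop = FALSE])
  strength
}

## Zhang-Suen morphological thinning of a logical mask to 1-pixel curves.
thin_mask <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift_pad0(m, -1L, 0L); p3 <- shift_pad0(m, -1L, 1L)
      p4 <- shift_pad0(m, 0L, 1L);  p5 <- shift_pad0(m, 1L, 1L)
      p6 <- shift_pad0(m, 1L, 0L);  p7 <- shift_pad0(m, 1L, -1L)
      p8 <- shift_pad0(m, 0L, -1L); p9 <- shift_pad0(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (phase == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

## integer shift with zero padding (for neighbourhood logic)
shift_pad0 <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[which(rok), which(cok)] <- x[rs[rok], cs[cok], drop = FALSE]
  out
}

## 8-connected component labelling of a logical mask (union-find).
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  on <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(on) == 0L) return(lab)
  parent <- seq_along(on)
  pos <- integer(nr * nc)
  pos[on] <- seq_along(on)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r <- (on - 1L) %% nr + 1L
  cc <- (on - 1L) %/% nr + 1L
  for (d in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L))) {
    r2 <- r + d[1]; c2 <- cc + d[2]
    ok <- which(r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc)
    lin <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- pos[lin] > 0L
    i1 <- ok[hit]          # index into `on` of the current pixel
    i2 <- pos[lin[hit]]    # index into `on` of its neighbour
    for (k in seq_along(i1)) {
      a <- find(i1[k]); b <- find(i2[k])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_along(on), find, integer(1))
  lab[on] <- match(roots, unique(roots))
  lab
}
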