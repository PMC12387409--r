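## Coarse-to-fine detection pipeline:
##   (1) multi-scale, multi-position enhanced-wavelet accumulation, fusion
##       and DoG sharpening;
##   (2) Zernike moments at every coarse candidate pixel;
##   (3) adaptive kt / lt thresholds and gating;
##   (4) sub-pixel mapping of the accepted candidates.

#' Pipeline configuration
#'
#' Collects and validates every tunable of the detector.  Defaults follow
#' the reference operating point for 400x400 ring images: scales
#' \{3, 4, 6\}, position step 6, 9x9 Zernike template, and both adaptive
#' thresholds active.
#'
#' @param scales wavelet scale factors (sigma, pixels).
#' @param step position step: side of the shift block per scale.
#' @param center_shifts centre the shift lattice (default `TRUE`); see
#'   [accumulate_shifted_responses()].
#' @param target_radius,bandwidth radial modulation R and delta per scale
#'   (recycled); default equal to `scales`, tying the annular band to the
#'   scale so each kernel stays compact.
#' @param radial_term radial deviation convention, see
#'   [radial_enhancement_kernel()].
#' @param dog_sigma length-2 vector (sigma1, sigma2) of the DoG filter.
#' @param size Zernike template side N (odd, default 9).
#' @param subsampling template integration subsampling (default 64).
#' @param min_component minimum coarse-edge component size in pixels.
#' @param coarse_method coarse extraction rule, see [extract_coarse_edges()].
#' @param moment_source `"image"` (default): moments of the input
#'   intensities; `"response"`: moments of the normalized DoG-sharpened
#'   response.
#' @param moment_smooth_sigma Gaussian pre-smoothing (pixels) applied to
#'   the moment source image; 0 disables.  The default 1 px suppresses
#'   pixel-noise jitter in the moment estimates without displacing edges.
#' @param curvature_sign sign of the curvature term in the distance
#'   threshold, see [distance_threshold_field()].
#' @param keep_fields retain intermediate fields in the result object
#'   (needed by [refine_at()] and `--save-intermediates`).
#' @return a list of class `"edge_detect_control"`.
#' @export
edge_detect_control <- function(scales = c(3, 4, 6),
                                step = 6L,
                                center_shifts = TRUE,
                                target_radius = scales,
                                bandwidth = scales,
                                radial_term = c("r", "r2"),
                                dog_sigma = c(1, 2),
                                size = 9L,
                                subsampling = 64L,
                                min_component = 5L,
                                coarse_method = c("zero_crossing", "magnitude"),
                                moment_source = c("image", "response"),
                                moment_smooth_sigma = 1,
                                curvature_sign = 1,
                                keep_fields = TRUE) {
  radial_term <- match.arg(radial_term)
  coarse_method <- match.arg(coarse_method)
  moment_source <- match.arg(moment_source)
  if (length(scales) < 1L || any(scales <= 0)) stop("'scales' must be positive")
  if (size %% 2L == 0L) stop("'size' must be odd")
  if (length(dog_sigma) != 2L || dog_sigma[1] >= dog_sigma[2])
    stop("'dog_sigma' must be (sigma1, sigma2) with sigma1 < sigma2")
  target_radius <- rep_len(target_radius, length(scales))
  bandwidth <- rep_len(bandwidth, length(scales))
  structure(list(scales = scales, step = as.integer(step),
                 center_shifts = center_shifts,
                 target_radius = target_radius, bandwidth = bandwidth,
                 radial_term = radial_term, dog_sigma = dog_sigma,
                 size = as.integer(size), subsampling = as.integer(subsampling),
                 min_component = as.integer(min_component),
                 coarse_method = coarse_method, moment_source = moment_source,
                 moment_smooth_sigma = moment_smooth_sigma,
                 curvature_sign = curvature_sign, keep_fields = keep_fields),
            class = "edge_detect_control")
}

## Coerce an input image to a [0, 1] grayscale matrix.
as_gray01 <- function(image) {
  if (length(dim(image)) == 3L) {
    ch <- dim(image)[3]
    message("non-grayscale input: converting by luminance")
    if (ch >= 3L) {
      image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
    } else {
      image <- image[, , 1]
    }
  }
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image must be finite")
  mx <- max(image)
  if (mx > 1) {
    ## integer-coded input: rescale by the dtype maximum, not per-image range
    den <- if (mx <= 255) 255 else 65535
    image <- image / den
  }
  image
}

#' Detect sub-pixel edges
#'
#' Runs the full coarse-to-fine pipeline on a grayscale image and returns
#' the accepted sub-pixel edge points together with all candidates and
#' (optionally) the intermediate fields.  The detector is deterministic
#' for a fixed input and configuration.
#'
#' Coordinates are 1-based: `col`/`xs` along the x (column) axis, `row`/
#' `ys` along the y (row) axis, matching R's matrix indexing at pixel
#' centres.
#'
#' @param image numeric matrix (or 3-channel array, converted by
#'   luminance).  Values above 1 are assumed 8- or 16-bit coded and are
#'   rescaled by the dtype maximum.
#' @param control a [edge_detect_control()] configuration.
#' @return object of class `"placido_edges"`: list with `points` (accepted
#'   points: `xs`, `ys`, `k`, `l`, `theta`, `row`, `col`), `candidates`
#'   (all candidates with thresholds and flags), `n_candidates`,
#'   `image_dim`, `control`, and `fields` when `keep_fields = TRUE`.
#' @examples
#' img <- make_binary_circle(width = 128, height = 128,
#'                           center = c(64, 64), radius = 40, supersample = 4)
#' \donttest{
#' det <- detect_subpixel_edges(img)
#' det
#' }
#' @export
detect_subpixel_edges <- function(image, control = edge_detect_control()) {
  image <- as_gray01(image)
  fe <- tryCatch(run_frontend(image, control), error = function(e) {
    if (grepl("degenerate", conditionMessage(e))) NULL else stop(e)
  })
  if (is.null(fe)) {
    warning("degenerate image: no edge response; empty result")
    return(structure(list(points = empty_points(),
                          candidates = cbind(empty_points(),
                                             kt = numeric(0), lt = numeric(0),
                                             accepted = logical(0)),
                          n_candidates = 0L, image_dim = dim(image),
                          control = control, fields = NULL),
                     class = "placido_edges"))
  }
  coarse <- extract_coarse_edges(fe$enhanced,
                                 min_component = control$min_component,
                                 method = control$coarse_method)
  st <- moment_stage(image, fe, control)
  cand_pix <- which(coarse$mask, arr.ind = TRUE)
  if (nrow(cand_pix) == 0L) {
    warning("empty candidate set")
    pts <- empty_points()
    cand <- cbind(pts, kt = numeric(0), lt = numeric(0),
                  accepted = logical(0))
  } else {
    cand <- refine_pixels(cand_pix[, 1], cand_pix[, 2], st, control)
    pts <- cand[cand$accepted,
                c("xs", "ys", "k", "l", "theta", "row", "col")]
    rownames(pts) <- NULL
  }
  structure(list(points = pts, candidates = cand,
                 n_candidates = nrow(cand),
                 image_dim = dim(image), control = control,
                 fields = if (control$keep_fields)
                   c(fe, list(mask = coarse$mask,
                              coarse = coarse,
                              z00 = st$z00, z11 = st$z11, z20 = st$z20,
                              kt = st$kt, lt = st$lt))),
            class = "placido_edges")
}

## Front-end: per-scale accumulation, fusion, DoG sharpening.
run_frontend <- function(image, control) {
  responses <- vector("list", length(control$scales))
  for (i in seq_along(control$scales)) {
    kern <- enhanced_mhw_kernel(control$scales[i],
                                target_radius = control$target_radius[i],
                                bandwidth = control$bandwidth[i],
                                radial_term = control$radial_term)
    responses[[i]] <- accumulate_shifted_responses(
      image, kern, step = control$step, center = control$center_shifts)$response
  }
  fused <- fuse_scales(responses)
  dk <- dog_kernel(control$dog_sigma[1], control$dog_sigma[2])
  enhanced <- enhance_with_dog(fused$total, dk)
  list(responses = responses, total = fused$total,
       weights = fused$weights, enhanced = enhanced)
}

## Moment and threshold fields shared by detection and refinement.
moment_stage <- function(image, fe, control) {
  src <- if (control$moment_source == "image") image else normalize01(fe$enhanced)
  if (control$moment_smooth_sigma > 0)
    src <- convolve2(src, gaussian_kernel(control$moment_smooth_sigma))
  masks <- zernike_masks(control$size, control$subsampling)
  mom <- compute_moments(src, masks)
  gt <- gray_threshold_field(mom$z11, mom$z20)
  dt <- distance_threshold_field(normalize01(fe$enhanced),
                                 size = control$size,
                                 curvature_sign = control$curvature_sign)
  list(z00 = mom$z00, z11 = mom$z11, z20 = mom$z20,
       kt = gt$kt, lt = dt$lt, gk = gt$gk, lk = dt$lk)
}

## Parameter recovery + gating + sub-pixel mapping at given pixels.
refine_pixels <- function(row, col, st, control) {
  idx <- cbind(row, col)
  par <- edge_parameters(st$z00[idx], st$z11[idx], st$z20[idx])
  sp <- subpixel_coordinates(row, col, par$l, par$theta, control$size)
  cand <- data.frame(xs = sp$xs, ys = sp$ys, k = par$k, l = par$l,
                     h = par$h, theta = par$theta, row = row, col = col,
                     flat = par$flat, model_violation = par$model_violation)
  gate_candidates(cand, st$kt, st$lt)
}

empty_points <- function() {
  data.frame(xs = numeric(0), ys = numeric(0), k = numeric(0),
             l = numeric(0), theta = numeric(0),
             row = integer(0), col = integer(0))
}

#' Refine given pixels through the detector's sub-pixel stage
#'
#' Computes the Zernike step-edge refinement (and threshold gating flags)
#' of arbitrary integer pixel positions, reusing the moment and threshold
#' fields stored in a detection result.  This is how the evaluation module
#' obtains the detector's sub-pixel coordinate *of* a chosen test point,
#' mirroring per-point accuracy protocols.
#'
#' @param object a `"placido_edges"` result with `keep_fields = TRUE`.
#' @param pixels data.frame or matrix with columns `row`, `col` (or `y`,
#'   `x`).
#' @return data.frame as `object$candidates` for the requested pixels.
#' @export
refine_at <- function(object, pixels) {
  stopifnot(inherits(object, "placido_edges"))
  if (is.null(object$fields))
    stop("detection was run with keep_fields = FALSE")
  pixels <- as.data.frame(pixels)
  if (!is.null(pixels$y) && is.null(pixels$row)) pixels$row <- pixels$y
  if (!is.null(pixels$x) && is.null(pixels$col)) pixels$col <- pixels$x
  st <- object$fields
  refine_pixels(as.integer(pixels$row), as.integer(pixels$col),
                st, object$control)
}

#' @export
print.placido_edges <- function(x, ...) {
  cat("Sub-pixel edge detection\n")
  cat(sprintf("  image: %d x %d   candidates: %d   accepted: %d\n",
              x$image_dim[1], x$image_dim[2], x$n_candidates,
              nrow(x$points)))
  invisible(x)
}

#' @export
summary.placido_edges <- function(object, ...) {
  p <- object$points
  cat("Sub-pixel edge detection\n")
  cat(sprintf("  image %d x %d, scales {%s}, step %d, N = %d\n",
              object$image_dim[1], object$image_dim[2],
              paste(object$control$scales, collapse = ", "),
              object$control$step, object$control$size))
  cat(sprintf("  candidates: %d, accepted: %d (%.1f%%)\n",
              object$n_candidates, nrow(p),
              if (object$n_candidates) 100 * nrow(p) / object$n_candidates else 0))
  if (nrow(p)) {
    cat(sprintf("  step height k: median %.3f   |l|: median %.3f\n",
                stats::median(p$k), stats::median(abs(p$l))))
  }
  invisible(object)
}

#' @export
as.data.frame.placido_edges <- function(x, ...) x$points

#' Plot detected sub-pixel edge points
#'
#' Displays the image (grayscale) with the accepted sub-pixel points
#' overlaid.
#'
#' @param x a `"placido_edges"` object.
#' @param image optional image matrix to use as backdrop.
#' @param cex,col point appearance.
#' @param ... passed to [graphics::points()].
#' @export
plot.placido_edges <- function(x, image = NULL, cex = 0.3, col = "red", ...) {
  d <- x$image_dim
  graphics::plot(NA, xlim = c(1, d[2]), ylim = c(d[1], 1), asp = 1,
                 xlab = "x (column)", ylab = "y (row)")
  if (!is.null(image)) {
    img <- as_gray01(image)
    graphics::rasterImage(grDevices::as.raster(img), 1, d[1], d[2], 1)
  }
  graphics::points(x$points$xs, x$points$ys, pch = 16, cex = cex, col = col, ...)
  invisible(x)
}
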