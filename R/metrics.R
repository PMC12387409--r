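## Evaluation: sample test points on a known circle, score detected
## sub-pixel points against them, and measure noise robustness.

#' Sample integer test points on a rasterized circle boundary
#'
#' Draws `n` distinct integer pixel positions uniformly (seeded) from the
#' pixels whose centre lies within `tol` pixels of the circle.  The
#' default `tol = 1/6` px keeps the sample on the best-rasterized ring
#' (every published benchmark point of this protocol satisfies it); pass
#' `tol = 0.5` for the loose one-pixel band.
#'
#' @param center circle centre `(cx, cy)`.
#' @param radius circle radius in pixels.
#' @param n number of points.
#' @param dim image dimensions `(rows, cols)` bounding the pixels.
#' @param seed optional RNG seed (state restored on exit).
#' @param tol boundary membership tolerance in pixels.
#' @return data.frame with integer columns `x`, `y`.
#' @export
sample_circle_points <- function(center = c(200, 200), radius = 150,
                                 n = 20L, dim = c(400L, 400L),
                                 seed = NULL, tol = 1 / 6) {
  if (n < 1L) stop("'n' must be at least 1")
  g <- coord_grids(dim[2], dim[1])
  r <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  cand <- which(abs(r - radius) <= tol, arr.ind = TRUE)
  if (nrow(cand) < n)
    stop("fewer than 'n' boundary pixels at this tolerance")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sel <- cand[sample.int(nrow(cand), n), , drop = FALSE]
  data.frame(x = as.integer(sel[, 2]), y = as.integer(sel[, 1]))
}

#' Score detected sub-pixel points against reference points
#'
#' Matches each reference ("actual") point to its nearest detected
#' sub-pixel point (Euclidean distance, ties broken by order) and reports
#' per-point coordinate errors `(|xs - x|, |ys - y|)`, Euclidean distance
#' errors, their summary statistics (sample standard deviation, divisor
#' n-1), and the p-value of a paired two-sided t-test of the matched
#' against the actual coordinates (x and y pairs pooled; zero-variance
#' differences give p = 1 by convention).
#'
#' @param actual data.frame with columns `x`, `y`.
#' @param detected a `"placido_edges"` object, or data.frame with columns
#'   `xs`, `ys`.
#' @param max_match warn when a matched distance exceeds this (gross
#'   failure flag), default 3 px.
#' @return object of class `"edge_error_report"`.
#' @export
match_and_score <- function(actual, detected, max_match = 3) {
  if (inherits(detected, "placido_edges")) detected <- detected$points
  if (nrow(detected) == 0L) stop("empty detected point set")
  dx <- outer(actual$x, detected$xs, "-")
  dy <- outer(actual$y, detected$ys, "-")
  D <- sqrt(dx^2 + dy^2)
  j <- apply(D, 1L, which.min)
  matched <- detected[j, c("xs", "ys")]
  ex <- abs(matched$xs - actual$x)
  ey <- abs(matched$ys - actual$y)
  derr <- sqrt((matched$xs - actual$x)^2 + (matched$ys - actual$y)^2)
  if (any(derr > max_match))
    warning(sum(derr > max_match), " matches farther than ", max_match, " px")
  diffs <- c(matched$xs - actual$x, matched$ys - actual$y)
  p <- if (stats::sd(diffs) == 0) 1 else
    stats::t.test(c(matched$xs, matched$ys), c(actual$x, actual$y),
                  paired = TRUE)$p.value
  structure(list(n_points = nrow(actual),
                 per_point = data.frame(x = actual$x, y = actual$y,
                                        xs = matched$xs, ys = matched$ys,
                                        ex = ex, ey = ey, dist = derr),
                 mean = mean(derr), max = max(derr), min = min(derr),
                 sd = stats::sd(derr), p_value = p),
            class = "edge_error_report")
}

#' @export
print.edge_error_report <- function(x, ...) {
  cat(sprintf("Edge error report (%d points)\n", x$n_points))
  cat(sprintf("  distance error: mean %.4f  max %.4f  min %.4f  sd %.4f px\n",
              x$mean, x$max, x$min, x$sd))
  cat(sprintf("  paired t-test p-value: %.4f\n", x$p_value))
  invisible(x)
}

#' Change in mean distance error under noise
#'
#' Runs the full pipeline on a clean and a degraded version of the same
#' scene, scores both against the same reference points (each point
#' refined through the detector's sub-pixel stage, see [refine_at()]), and
#' returns the difference of mean distance errors (noisy minus clean).
#'
#' @param image clean image matrix.
#' @param noisy degraded image with identical geometry.
#' @param points reference points (`x`, `y` data.frame), e.g. from
#'   [sample_circle_points()].
#' @param control detector configuration.
#' @return the delta in pixels, with attributes `clean` and `noisy`
#'   holding the two error reports.
#' @export
noise_robustness_delta <- function(image, noisy, points,
                                   control = edge_detect_control()) {
  rc <- score_at_points(detect_subpixel_edges(image, control), points)
  rn <- score_at_points(detect_subpixel_edges(noisy, control), points)
  structure(rn$mean - rc$mean, clean = rc, noisy = rn)
}

#' Score reference points through per-point refinement
#'
#' For each reference point the detector's sub-pixel coordinate *at that
#' pixel* is computed ([refine_at()]); points whose refinement fails the
#' adaptive gates fall back to the nearest accepted detection.  The
#' combined set is scored with [match_and_score()].
#'
#' @param det a `"placido_edges"` detection run with `keep_fields = TRUE`.
#' @param points data.frame with columns `x`, `y`.
#' @return an `"edge_error_report"`.
#' @export
score_at_points <- function(det, points) {
  ref <- refine_at(det, data.frame(row = points$y, col = points$x))
  pool <- rbind(det$points,
                ref[ref$accepted, c("xs", "ys", "k", "l", "theta", "row", "col")])
  if (nrow(pool) == 0L) stop("no accepted points to score against")
  match_and_score(points, pool)
}

#' Reproduce the synthetic-circle accuracy experiment
#'
#' Generates the 400x400 circle benchmark (centre (200, 200), radius 150,
#' area-sampled boundary), runs the full detector once, and scores 20
#' seeded boundary points per evaluation seed.  Optionally repeats the
#' scoring on noise-degraded copies (i.i.d. Gaussian noise, sd 0.2,
#' clipped) to measure the noise-robustness delta.
#'
#' @param eval_seeds integer vector: one 20-point sample per seed; the
#'   reported statistics are averaged across seeds.
#' @param noise_seeds optional integer vector of noise realizations.
#' @param n points per sample (default 20).
#' @param noise_sd Gaussian noise sd (default 0.2).
#' @param supersample boundary rendering of the fixture (default 16;
#'   1 gives the hard center-sampled binary disc).
#' @param tol boundary-membership tolerance (default 1/6).
#' @param control detector configuration.
#' @return list with `stats` (seed-averaged `mean`, `max`, `min`, `sd`),
#'   `per_seed` (matrix), `delta` (seed-averaged noise delta or `NULL`),
#'   `deltas`, and the clean `detection`.
#' @export
circle_benchmark <- function(eval_seeds = 1:10, noise_seeds = NULL,
                             n = 20L, noise_sd = 0.2, supersample = 16L,
                             tol = 1 / 6,
                             control = edge_detect_control()) {
  img <- make_binary_circle(supersample = supersample)
  det <- detect_subpixel_edges(img, control)
  score_seeds <- function(d) {
    t(vapply(eval_seeds, function(s) {
      pts <- sample_circle_points(n = n, seed = s, tol = tol)
      rep_ <- score_at_points(d, pts)
      c(mean = rep_$mean, max = rep_$max, min = rep_$min, sd = rep_$sd)
    }, numeric(4)))
  }
  per_seed <- score_seeds(det)
  stats <- colMeans(per_seed)
  deltas <- NULL
  if (!is.null(noise_seeds)) {
    deltas <- vapply(noise_seeds, function(ns) {
      noisy <- add_gaussian_noise(img, noise_sd, seed = ns)
      dn <- detect_subpixel_edges(noisy, control)
      mean(score_seeds(dn)[, "mean"]) - stats[["mean"]]
    }, numeric(1))
  }
  list(stats = stats, per_seed = per_seed,
       delta = if (!is.null(deltas)) mean(deltas), deltas = deltas,
       detection = det)
}
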