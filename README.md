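# placidoedge

Sub-pixel edge detection for corneal Placido ring images.

Placido-disc corneal topographers image concentric rings reflected off the
cornea; corneal curvature — and with it diagnoses such as keratoconus — is
reconstructed from the geometry of the imaged ring edges.  That makes edge
localization accuracy the limiting factor of the whole instrument, and the
images are hard targets: narrow ring spacing, eyelash shadows and specular
spots.  `placidoedge` implements a coarse-to-fine detector for this setting:

1. **Front-end** — a Mexican Hat (Ricker) wavelet with radial Gaussian
   modulation, `h_σ(x,y) = (1/σ²)(2 − r²/σ²) e^{−r²/2σ²} · e^{−(r−R)²/δ²}`,
   convolved at multiple scales (default σ ∈ {3, 4, 6}) and accumulated over
   a block of integer shifts (position step 6); the scale responses are
   fused with dispersion-derived weights and sharpened with a
   difference-of-Gaussians filter.  Coarse edges are the strength-gated
   zero-crossings of the result, thinned to 1-px curves.
2. **Sub-pixel stage** — at every coarse pixel the order (0,0), (1,1), (2,0)
   Zernike moments of a 9×9 window invert the ideal step-edge model:
   `θ = arg z11`, `l = z20/|z11|`, `k = 3|z11| / (2(1−l²)^{3/2})`, and the
   edge point moves to `(x + (Nl/2)cosθ, y + (Nl/2)sinθ)`.
3. **Double adaptive gate** — a gray-level threshold
   `kt = (G² + σ² + ln(1+υ))/5` from local gradient/variance statistics, and
   a distance threshold `lt = 2/N + 0.2·lk` from the largest absolute
   Hessian eigenvalue; accepted points satisfy `k ≥ kt` and `|l| ≤ lt`.

Everything is exposed both as R functions (kernels, moment templates,
threshold fields, fixture generators, scoring) and as a small CLI
(`detect`, `synth`, `eval`).

## Worked example

```r
library(placidoedge)

img <- make_binary_circle(supersample = 16)   # 400x400 disc, r = 150
det <- detect_subpixel_edges(img)
summary(det)
#> Sub-pixel edge detection
#>   image 400 x 400, scales {3, 4, 6}, step 6, N = 9
#>   candidates: 848, accepted: 804 (94.8%)
#>   step height k: median 0.914   |l|: median 0.082

head(round(as.data.frame(det), 3))
#>       xs      ys     k      l theta row col
#> 1 50.623 186.967 0.918 -0.084 0.086 187  51
#> 2 50.556 187.965 0.917 -0.099 0.079 188  51
#> 3 50.495 188.964 0.916 -0.112 0.072 189  51
```

The detector finds 848 coarse candidates on the circle, accepts 804 of them,
and each accepted row carries the sub-pixel coordinate `(xs, ys)`, the step
height `k` (≈ 1 for a unit-contrast edge), the unit-disc offset `l` and the
edge normal `theta`.  Scoring 20 seeded integer boundary points against the
detection:

```r
pts <- sample_circle_points(n = 20, seed = 1)
score_at_points(det, pts)
#> Edge error report (20 points)
#>   distance error: mean 0.0715  max 0.1293  min 0.0121  sd 0.0307 px
#>   paired t-test p-value: 0.2650
```

A mean distance error of 0.07 px means the detector recovers the circle an
order of magnitude finer than the pixel grid.  See the vignette
(`vignettes/placido-subpixel-edges.Rmd`) for the model, every tunable
parameter and the design decisions behind the defaults.

### Command line

```sh
inst/scripts/placidoedge synth circle --out circle.png --supersample 4
inst/scripts/placidoedge detect --input circle.png --output points.csv
inst/scripts/placidoedge eval --input circle.png --report report.json --seed 1
```

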