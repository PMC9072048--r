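# curvseg

Statistical segmentation of bright curvilinear structures — vessels,
ducts, cracks, tubular anatomy — in 2-D grayscale images, for image
analysts who need a fully inspectable, trainable-weight-free pipeline
with a reproducible synthetic benchmark.

## Method

The pipeline combines four classical components:

1. **Gray-level mixture model.** The histogram is modeled as one
   Rayleigh plus Gaussian components,

   p(t) = w₀ (t/σ_R²) exp(−t²/2σ_R²) + Σₖ wₖ N(t; μₖ, σₖ²),

   with the Rayleigh and the first Gaussians as *background* and the
   last Gaussian as the bright *target*. Fitting is histogram-weighted
   EM — exactly per-pixel EM at per-gray-level cost.
2. **Multiscale Hessian line similarity.** γ-normalized (γ = 2)
   second-derivative-of-Gaussian filtering over a scale grid; the
   Frangi eigenvalue measure
   v = exp(−(λ₁/λ₂)²/2β_r²)·(1 − exp(−(λ₁²+λ₂²)/2c_r²)) for λ₂ < 0
   is maximized over scales, and the argmax scale estimates local
   width.
3. **MRF + ICM.** Labels minimize
   U(y) = Σᵢ e_{yᵢ}(xᵢ) + β·#{disagreeing 4-neighbor pairs}
   + α·Σᵢ mismatch(yᵢ, vᵢ),
   by deterministic raster-order iterated conditional modes from the
   maximum-likelihood initialization; the per-sweep energy trace is
   provably non-increasing.
4. **Boundary refinement.** Boundary pixels take the label found a
   step of r (scaled, rounded) along one of eight compass directions
   toward their nearest same-label interior pixel; interior pixels are
   bit-preserved.

A seeded phantom generator (tree-structured strokes of varying width
over a Rayleigh + two-Gaussian background, plus Gaussian noise on the
normalized [0,1] scale), confusion metrics, a gray-level k-means
baseline and a noise-robustness harness make the whole pipeline
testable without proprietary data. See `vignettes/curvseg-methods.Rmd`
for assumptions, defaults and limitations.

## Worked example

```r
library(curvseg)

cfg <- phantom_config(size = c(128L, 128L), noise_variance = 0.02, seed = 1)
ph  <- generate_phantom(cfg)
ph
#> <phantom_pair> 128x128, 8-bit, foreground fraction 0.0794, seed 1

seg <- segment_image(ph$image)
seg
#> <segmentation_result> 128x128, 1567 feature pixels, 7 ICM sweep(s)

confusion_metrics(seg$labels, ph$truth)
#> <metric_report> accuracy 0.9829  sensitivity 0.9946  specificity 0.9819
#>                 iou_bg 0.9814  iou_fg 0.8221  miou 0.9018

confusion_metrics(kmeans_gray(ph$image), ph$truth)
#> <metric_report> accuracy 0.6207  sensitivity 0.9977  specificity 0.5882
#>                 iou_bg 0.5881  iou_fg 0.1728  miou 0.3804
```

The phantom hides a 7.9%-foreground stroke tree under noise; the full
pipeline recovers it at 98.3% pixel accuracy while gray-only k-means,
which splits the two background modes instead of isolating the bright
minority, reaches 62.1%.

The same stages are scriptable from the shell through the thin wrapper
`inst/cli/curvseg`:

```sh
curvseg simulate --seed 42 --out-dir phantoms/
curvseg segment  --in phantoms/phantom.png --out mask.png --report report.json
curvseg evaluate --pred mask.png --truth phantoms/truth.png --out metrics.json
curvseg robustness --out robustness.csv --variances 0,0.02,0.06,0.10
```

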