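# fibrilmap

Quantitative image analysis for fibrillar hydrogel networks imaged by
scanning electron microscopy — in particular interpenetrating networks of
amyloid protein fibrils (AF) and a fibrillar polysaccharide (PHY, gellan
gum). The package answers two questions about such micrographs:

* **How wide are the fibers?** An automated five-stage pipeline —
  intensity segmentation, exact Euclidean distance transform (EDT),
  topology-preserving skeletonization, centerline refinement, local width
  measurement — yields a width value at every centerline pixel. At a
  centerline pixel with distance-map value *d*, the local width is
  *w = 2d − 1* px (pixel-center convention), converted to nm when the pixel
  size is known. Widths are clustered by one-dimensional k-means into
  *thin / medium / thick* segments; the medium cluster, reported as
  mean ± sd (e.g. `21 ± 2 nm`), is the per-sample headline width.
* **Which regions are protein, which polysaccharide?** A sliding-window
  patch classifier: 224×224 crops, a stratified 80/20 train/validation
  split (grouped by source image to prevent near-duplicate leakage), a
  compact convolutional network trained from scratch, confusion-matrix
  evaluation, and per-crop maximum-score labels rendered as a color-coded
  composition map (AF magenta, PHY blue) with class-fraction histograms.

Because such studies rarely deposit raw micrographs, the package includes a
synthetic fibrous-image generator with exact ground truth (per-fiber
centerline coordinates, widths, class and region labels): fibers are
bounded-turning-angle random walks with constant per-fiber width drawn from
a configurable mixture, rasterized by pixel coverage, plus spatially
correlated texture noise. Every pipeline stage is validated against this
ground truth and against independent brute-force oracles.

## Worked example

Generate a synthetic micrograph with three width populations, run the width
pipeline, and report the cluster summary:

```r
library(fibrilmap)

spec <- fiber_spec(
  n_fibers = 6,
  width_modes = data.frame(mean = c(5, 11, 21), sd = c(1, 1, 1),
                           weight = c(1, 1, 1) / 3),
  curvature = 300,                      # persistence length, px
  fiber_intensity = 0.8, background_intensity = 0.15,
  texture = list(noise_sd = 0.05, corr_len = 1.5),
  image_shape = c(448, 448), seed = 7)

img <- generate_fiber_image(spec)$image
attr(img, "pixel_size") <- 2            # nm per pixel

result <- analyze_image(img)
result$clusters
#> width clusters (k = 3):
#>    name     mean         sd count    lower    upper
#>    thin 10.00666 1.01863097   565     -Inf 16.04584
#>  medium 22.08502 0.45750788  1445 16.04584 32.06810
#>   thick 42.05118 0.08271686   290 32.06810      Inf
#> headline (medium): 22.1 ± 0.5 nm
```

The three cluster means sit at the nm equivalents of the generated width
modes (5, 11, 21 px at 2 nm/px → 10, 22, 42 nm); the headline `22.1 ± 0.5
nm` is the medium-cluster mean ± sd over centerline pixels. `result$widths` is
the per-pixel width table, `result$histogram` the binned distribution, and
`render_width_colormap(img, result$widths, result$clusters)` draws the
three-color width overlay.

Train the patch classifier on the packaged five-class reference conditions
and map a hybrid image:

```r
ds    <- generate_class_dataset(demo_class_specs(), n_images_per_class = 20,
                                seed = 101)
ps    <- patches_from_dataset(ds)       # 1600 patches of 224 x 224
split <- split_dataset(ps, 0.8, seed = 101)
model <- train_classifier(ps, split,
                          small_cnn_config(n_classes = 5, seed = 1))
evaluate_classifier(model, ps, split$val_ids)
#>             predicted
#> true         APO BLG LYS PHY PHY_coarse
#>   APO         63   1   0   0          0
#>   BLG          0  62   2   0          0
#>   LYS          0   1  62   0          1
#>   PHY          0   0   0  64          0
#>   PHY_coarse   0   0   0   0         64
#> overall accuracy: 98.4%
```

The only visible confusion is between BLG and LYS, the pair generated to
resemble each other most closely. A command-line wrapper for all of this is
installed at `inst/scripts/fibrilmap`
(`fibrilmap {synth, width, train, map, run}`).

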