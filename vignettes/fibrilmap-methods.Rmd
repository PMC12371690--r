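---
title: "Quantifying fibrillar hydrogel networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrillar hydrogel networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilmap)
```

# The problem

Interpenetrating-network hydrogels built from amyloid protein fibrils (AF)
and a fibrillar polysaccharide such as gellan gum (PHY) are imaged by
high-resolution scanning electron microscopy. Two quantitative questions
arise from such micrographs:

1. **How wide are the fibers?** Fiber width distributions characterize the
   self-assembly of each protein and the hybrid networks.
2. **Which regions of a hybrid micrograph are protein and which are
   polysaccharide?** The two fiber types are hard to tell apart by eye but
   differ in fine textural detail.

`fibrilmap` implements an automated pipeline for each question, plus a
synthetic micrograph generator with exact ground truth so both pipelines can
be validated end to end without access to any particular instrument's
images.

# Fiber-width pipeline

The pipeline has five stages, each exposed as a function:

1. **Segmentation** (`segment_fibers`). Fibers are the brighter phase;
   a global intensity threshold separates them from the darker background.
   The default threshold is Otsu's method (256 gray levels, maximal
   between-class variance); a fixed threshold can be supplied instead. The
   threshold used is recorded on the mask. A constant image yields an empty
   mask with a warning, since no threshold separates anything.
2. **Euclidean distance transform** (`distance_transform`). Every foreground
   pixel receives the exact Euclidean distance (pixel centers) to the
   nearest background pixel. The image frame is treated as background —
   otherwise a fiber crossing the frame would have unbounded apparent
   width — and entries within one maximal width of the frame carry a
   `border` flag.
3. **Skeletonization** (`skeletonize`). Topology-preserving Zhang–Suen
   thinning reduces the mask to a single-pixel centerline. The
   implementation iterates over foreground index vectors, so cost scales
   with fiber area, not image area.
4. **Centerline refinement** (`refine_centerline`). Small skeleton gaps are
   closed by a 3×3 dilation followed by re-thinning — applied only when the
   dilation actually merges skeleton fragments, because re-thinning an
   intact skeleton erodes its endpoints — and terminal branches shorter
   than `spur_length` (default 5 px) ending at a junction are pruned. The
   pass iterates to a fixed point, which makes refinement idempotent.
5. **Width measurement** (`measure_local_width`). At a centerline pixel with
   distance value $d$, the local width is $2d - 1$ px (pixel-center
   convention: exact on odd-width axis-aligned ribbons; `convention = "2d"`
   is available). Two practical corrections matter:
   * the value of $d$ is read as the maximum of the distance map within
     2 px of the centerline pixel. Thinning leaves a zigzag centerline on
     oblique fibers whose pixels sit off the medial axis, and the ridge
     value itself oscillates with lattice phase; both bias the raw reading
     low by up to ~1 px. On axis-aligned ribbons the ridge is flat and the
     reading is unchanged.
   * entries are flagged where the width is not defined by clean local
     geometry: within one local half-width of a skeleton junction
     (crossings inflate the distance map — visually, clumped fibers) and
     within one half-width of a skeleton endpoint (the map tapers at fiber
     termini). Junction-zone entries are excluded from cluster statistics
     by default.

## Width clustering and reporting

`cluster_widths` runs one-dimensional k-means (Lloyd) on the width values
with deterministic initialization at the k quantile-band midpoints
(k = 3 by default). Clusters are renamed `thin`, `medium`, `thick` by
ascending mean. This three-way partition reflects how fibrillar networks
present in practice: a clean single-fiber population, together with
thinner fragments and thicker clumped/bundled segments. The medium cluster
is the headline per-sample statistic, reported as mean ± sd in the measured
unit, e.g. `21 ± 2 nm` (sd rounded to one significant digit, mean to the
same decimal place). The ± is the standard deviation of the member widths;
nothing else about its meaning is assumed.

`width_histogram` bins the same values; `render_width_colormap` paints local
widths over the grayscale image with either a continuous palette (clipped at
the 1st–99th percentile) or one discrete color per cluster, and
`write_overlay` embeds the color legend.

## Validation strategy and what it shows

Synthetic fibers are bounded-turning-angle random walks (persistence-length
parameterization) with a constant width per fiber drawn from a Gaussian
mixture and quantized to the nearest odd pixel count ≥ 3 px, rasterized by
pixel coverage: a pixel belongs to a fiber when its center lies within
width/2 of the centerline. On an axis-aligned fiber this gives exactly
`width` rows; on oblique fibers it keeps the band unbiased, at the cost of a
staircase boundary whose perpendicular chords can exceed the nominal width
by up to ~1.5 px locally.

The properties verified by the test suite:

* the distance transform agrees with brute-force nearest-background search
  to 10⁻⁶ on random masks up to 64×64 (it is exact);
* for widths 5–61 px, straight or curved at persistence ≥ 5× width, with
  texture noise, the median measured width is within ±1 px of truth
  (observed worst error ≈ 0.2 px);
* a three-mode width mixture (modes 5/20/60 px) pooled over 20 sparse
  synthetic images is recovered by `cluster_widths` with per-mode error
  below 5% of the realized mode means.

Passing these tests shows the geometry pipeline is accurate on images whose
ground truth is known exactly. It does not certify performance on real
micrographs, where segmentation quality (charging, coating, depth effects)
dominates; those artifacts are deliberately out of scope for the generator.

# Patch classifier

`crop_sliding_window` tiles an image into 224×224 patches (stride =
patch size by default for dataset building; half a patch for map
rendering). `split_dataset` makes a stratified 80/20 train/validation
split. The default assigns whole source images to one side
(`by_image = TRUE`): sliding-window crops from one micrograph are highly
similar, and letting them straddle the split inflates validation accuracy —
the classic leakage this data layout invites. The plain patch-level split is
available as a flag.

## Architecture

The classifier is a compact convolutional network trained from scratch:

* input: the patch block-averaged to 56×56 (224/4). Width and texture
  signatures of interest survive this reduction, and it keeps training on a
  single CPU core in the minutes range;
* four 3×3 convolution blocks (8, 16, 32, 32 filters), each convolution
  followed by per-channel batch normalization and ReLU; 2×2 max pooling
  after the first three blocks;
* a multi-scale head: global average **and** global max pooled features
  from every block, concatenated (176 features) into a dense softmax layer.
  Average-pooled block-1 features act as soft quantile statistics of
  intensity, and max-pooled deeper features capture peak texture responses —
  both are discriminative for fiber textures, and the concatenation lets
  the linear head use them directly;
* cross-entropy loss, Adam (lr 10⁻³), batch size 32, 10 epochs, early
  stopping on a validation-accuracy plateau (patience 3), best-epoch
  weights kept. No augmentation by default. Intensities are fed in absolute
  \[0, 1\] units (`standardize = FALSE`): absolute brightness is itself
  class information in this imaging mode; per-patch standardization is
  available for data where it is not.

Everything is implemented directly on BLAS matrix products (im2col
convolutions), so training is deterministic for a fixed data/config/seed
triple and requires no deep-learning runtime. A pretrained
transfer-learning backbone (e.g. a ResNet-50 with a replaced head) is a
natural alternative for real micrograph corpora but is out of scope for
this package.

## Evaluation and composition maps

`evaluate_classifier` produces the true-by-predicted confusion matrix with
overall and per-class accuracy. `classify_image` scores every crop of an
image independently (softmax score vectors summing to 1) and labels each
crop by its maximum prediction score. `render_class_map` resolves pixels in
overlapping crops by the crop whose center is nearest, blends the class
color over the grayscale image (amyloid-fiber classes magenta,
polysaccharide classes blue, configurable), and tabulates the fraction of
crops per class — the map plus histogram view used to compare, e.g.,
exterior versus interior regions of a hybrid gel disc.

## The five reference classes

`demo_class_specs()` defines the study conditions used by the tests and the
acceptance script: three amyloid-like classes — APO with a broad two-mode
width mixture (7 and 17 px), and a deliberately similar BLG/LYS pair
(width modes 15 vs 13 px, fiber intensity 0.80 vs 0.75, identical texture) —
plus a fine dense polysaccharide network (PHY, 5 px, short correlation
length) and a coarse bundled one (PHY_coarse, 25 px, long correlation
length). Twenty 1024×1024 images per class cut into non-overlapping 224×224
patches give a 1600-patch corpus (1280 train / 320 validation under the
image-grouped stratified split). The BLG/LYS pair is designed as the
hardest pair: their distributions overlap in width and differ modestly in
contrast, so residual confusion should concentrate there — and does.

Observed behavior at these conditions (recomputed by
`scripts/acceptance.R` and `tests/testthat/test-acceptance.R`): held-out
accuracy above 95% (observed 95.6–98.4% across training seeds), LYS
misclassification at most 5% with its errors assigned to BLG.

## Null and leakage controls

Two controls guard against self-deception:

* training on shuffled labels gives chance-level validation accuracy
  (within a binomial band);
* two classes whose generator parameters differ negligibly (background
  intensity gap of 10⁻⁶) are statistically indistinguishable, and training
  on them also ends at chance. As the between-class parameter gap shrinks
  to zero, achievable accuracy approaches chance — so a high reported
  accuracy reflects class signal, not leakage through the split or the
  generator.

# Synthetic generator: scope and limits

The generator emulates: bright curvilinear fibers over a darker background,
per-class width mixtures, persistence-length-controlled curvature,
spatially correlated Gaussian texture (white noise smoothed with a Gaussian
kernel of the stated correlation length, rescaled, added after
rasterization, clipped to \[0, 1\]), and hybrid composites where brighter
fibers occupy a smooth random region of prescribed exact pixel fraction
over a full-frame matrix network.

It does not emulate physical SEM effects — charging, depth of field,
coating grain, magnification-dependent contrast — nor fiber branching,
variable width along a fiber, or bundle mechanics. Classifier accuracies on
this synthetic corpus are therefore analogs of, not estimates of, accuracy
on instrument data; the classes' texture contrasts are free parameters, not
calibrated to the real materials.

# Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col) with pixel centers at integers in all
  public tables; masks use the image bounds.
* `cluster_widths` needs at least k distinct values and errors otherwise;
  ties in quantile initialization fall back to evenly spaced distinct
  values.
* Centerline pixels falling on background (distance 0) are skipped and
  counted in the `skipped` attribute.
* `af_region_fraction` must lie in (0, 1]; a fraction of exactly 1 means
  the overlay region is the whole frame; a matrix-only composite is
  requested with `af_spec = NULL`.
* Width tables, histograms and reports serialize numbers at full precision
  (17 significant digits), so write-then-read round trips are exact; every
  report carries the config hash and seed that produced it.
* All randomness flows from explicit integer seeds; identical (spec, seed)
  pairs reproduce bit-identical images, and fixed data/config/seed
  reproduces a training log exactly.

# Problem sizes used in the checks

The test suite and acceptance script run at desk scale by design: width
properties use 320–768 px images with 3 fibers per image (20 images for the
mixture); the classifier corpus is 100 images of 1024² (1600 patches); null
controls use 448² images with 80 patches. These sizes were chosen so that
each property is measured on ample statistics while the whole suite remains
a coffee-break run on one CPU core.

# Known limitations

* Widths are measured per centerline pixel, not per fiber: the package does
  not track individual fibers across junctions, so "how many fibers" and
  per-fiber statistics are out of scope.
* The 2d−1 width convention quantizes to odd pixel values on ideal ribbons;
  sub-pixel width estimation is not attempted.
* The junction- and endcap-zone exclusions are conservative: in very dense
  networks they can discard a large share of centerline pixels, which is
  visible in the cluster counts.
* The classifier assigns one label per crop; it is a patch classifier, not
  a pixel-level semantic segmenter, and boundary crops in hybrid images are
  genuinely mixed.
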