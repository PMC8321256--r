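---
title: "Compressing vegetation-index time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing vegetation-index time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multispectral satellite time series describe vegetation through spectral
indices — arithmetic combinations of band reflectances tuned to biophysical
attributes (chlorophyll, canopy structure, soil background, water).  A year
of monthly composites of 16 indices gives every pixel a 192-dimensional
feature vector (16 indices x 12 months).  These features are highly
correlated, and high dimensionality impairs clustering, visualization and
classification.  `vicomp` compresses the 192-vector to a few latent features
by self-supervised learning (autoencoders trained to reconstruct their own
input), then quantifies how much class-discriminative information survives
compression, against the classical supervised alternative of keeping the
top-k features by random-forest importance.

## Pipeline and models

### Spectral indices

Sixteen indices are computed per scene from six band roles (Blue, Green,
Red, RedEdge1, RedEdge3, NIR; Sentinel-2 bands B2/B3/B4/B5/B7/B8).  The
registry order is fixed and alphabetical: ARVI, EVI, GARI, GCI, GLI, GNDVI,
GRVI, MRENDVI, MRESR, MSAVI, NDVI, OSAVI, RENDVI, SAVI, SIPI, VARI.  Two
formula choices deserve note:

* **ARVI** is implemented in the Kaufman–Tanre form with gamma = 1,
  `(N - (2R - B)) / (N + (2R - B))`, because the source table's typeset
  fraction collapses ambiguously.
* **GCI** is implemented exactly as printed in the source table, `N/R - 1`,
  although the name ("Green") suggests `N/G - 1`; table fidelity wins and
  the choice is documented here.

A denominator with absolute value below `1e-12` masks only that index value
(the other 15 survive).  Reflectance outside `[-0.1, 2]` is treated as
corrupt and masks the whole pixel.  Index values are not clipped; the
encoder's per-feature standardization handles scale.

### Monthly median compositing

Scenes are grouped by calendar month (all years pooled into one
climatology), and each pixel/index cell takes the median over unmasked
observations; the even-count median is the mean of the two central order
statistics, computed explicitly as order statistics so results are bit-exact
against a sort-based oracle.  Cells with no valid observation are filled by
linear interpolation across months within the same index (nearest-value
extrapolation at the ends).  Temporal interpolation — rather than
cross-pixel filling — preserves each pixel's phenological shape, which is
exactly what the convolutional encoder consumes.  A pixel with an index
that has *no* valid month cannot be filled; it is flagged and excluded from
training.  The 192-band layout is month-major (`m01_ARVI ... m12_VARI`).

### Autoencoders

Inputs are z-scored per feature (mean/sd stored with the model;
zero-variance features are dropped and reinserted as constants at decode).
Two architectures, both with mean-squared reconstruction error, Adam
(learning rate 1e-3), batch size 256, at most 200 epochs with early
stopping on a held-out 5% validation split (patience 20), all
configurable:

* **AE** (dense): encoder 192 -> 128 -> 64 -> k with ReLU hidden layers and
  a linear bottleneck; decoder mirrored.
* **CAE** (convolutional): the 192-vector is read as a 12-step monthly
  sequence with 16 index channels.  Encoder: three 1-D convolutions over
  the month axis (channels 16->32->64->64, kernel 3, stride 2 on the first
  two), then one dense layer to k latents.  Decoder mirrored with
  nearest-neighbour x2 upsampling.  Convolving the *temporal* axis (not
  image space) is a deliberate interpretation: training pairs are per-pixel
  annual vectors, not image patches, so the local correlation available to
  a convolution is month-to-month.

The reference latent dimensions are k in {3, 5, 10}.  Training is exactly
reproducible from a seed (initialization, split and shuffling all derive
from it), and persistence round-trips bit-identically.

The 95/5 split is a random pixel split without spatial blocking, matching
the reference protocol.  Layer widths, kernel sizes and activations are not
recoverable from the source description ("trial and error"); the defaults
above are fixed, sensible choices and are exposed in the API.

### Evaluation

Labelled feature vectors are extracted at ground-truth points by direct
pixel lookup (0-based integer coordinates).  Three feature sets compete at
each k: CAE latents, AE latents, and the top-k columns by random-forest
impurity importance (ties broken by column order) — the supervised
classical baseline.  The baseline is supervised while the autoencoders are
self-supervised; that asymmetry is inherited from the protocol being
reproduced.

Classification performance is measured by bootstrap resampling: each of
`n_boot = 1000` iterations resamples the n points with replacement to size
n, splits that sample 75/25 (rows not drawn are not reused), fits a
random forest on the 75% and records overall accuracy on the 25% plus the
normalized importance vector.  The reference text conflates "with
replacement" and "75/25 split"; resample-then-split is the implemented
reading, and plain repeated splits are available via
`replacement = FALSE`.  Iterations whose test part has fewer than two
classes are redrawn (warned if over 10%).  The confidence interval is the
percentile interval computed as order statistics (inverse ECDF,
`sorted(x)[ceiling(n p)]`), so bounds are always elements of the accuracy
sample and widening the confidence never narrows the interval.

The random forest itself (Gini CART, bootstrap bagging,
`mtry = floor(sqrt(d))`, 500 trees by default, normalized
mean-decrease-impurity importance) is implemented in compiled code inside
the package because no random-forest package is available in the target
environment.

### Visualization

Three-dimensional scatter plots of the first three latents (one colour and
legend entry per class, deterministic palette) and 8-bit RGB false-colour
renderings of 3-band latent rasters.  Each RGB channel is linearly
stretched from its 2nd–98th percentile window to [0, 255] — the standard
remote-sensing display convention; a degenerate window renders mid-gray
127, masked pixels render 0, and latent dims 1, 2, 3 map to R, G, B.

## The synthetic world

No imagery or field data are deposited with the reference study, so the
package carries a generator that emulates the study region's 16 classes
(13 classes with 300 ground-truth points, Hydrangea Shrub 165, Salix Shrub
108, Tsuga ECF 107).  Each class is a seasonal greenness curve (baseline +
Gaussian bell over months) mixing a background spectrum (soil, wet soil or
water) with a green-vegetation spectrum: deciduous forests get a steep
summer NIR peak, evergreen conifers stay green year-round with small
offsets separating genera, alpine herbs have short sharp seasons, Water is
flat and dark in the NIR, Barren/Built-up is flat mid-reflectance.  Scenes
add independent Gaussian noise per band per observation (default sd 0.02,
a realistic post-atmospheric-correction reflectance noise), truncate to
[0, 1], and mask whole pixel-observations with probability
`cloud_fraction` (default 0.2) as a cloud analog.  The grid is tiled into
rectangular single-class regions (the "homogeneous area" analog) and
ground-truth points are distinct pixels inside each class's region.

What the generator does *not* emulate — and hence what a green test does
not establish: spatial autocorrelation and mixed pixels (pixels are
independent), within-class heterogeneity (every pixel of a class shares
one archetype trajectory), topographic and BRDF effects, per-year
phenological anomalies (one pooled climatology), and real cloud spatial
structure (masking is independent per pixel).  Two practical consequences
are worth knowing.  First, indices with reflectance denominators (GCI,
MRESR) develop heavy tails over dark classes (Water), so reconstruction
losses are dominated by a few extreme features; this mirrors real
behaviour of ratio indices over water.  Second, because within-class
variation is pure iid noise, class information saturates at low latent
dimension: accuracy rises clearly from k = 3 to 5 but the 5 -> 10 step is
often flat to within training noise, unlike real imagery where
within-class diversity keeps higher dimensions informative.  The
acceptance suite therefore checks the k-trend with a majority rule across
five seeds, and a flat step in this world is a known borderline case, not
a pipeline defect.

## Numerical choices

* Even-count medians: mean of the two central order statistics.
* Near-zero denominators (`|den| < 1e-12`): masked single values, never
  exceptions.
* Standardization round-trip accurate to 1e-9; zero-variance features
  dropped with a warning.
* Non-finite training loss aborts with a diagnostic rather than continuing.
* Percentile CIs are order statistics (both bounds members of the sample).
* All stochastic steps (simulation, splits, shuffling, forests, bootstrap)
  are seeded; the forest uses its own Mersenne Twister stream so C++ and R
  RNG use cannot interleave.

## Scaling of the shipped tests

The reference protocol (full Table-1 point counts, 1000 bootstrap
iterations, 500 trees) runs for hours on one CPU.  The shipped acceptance
tests run the identical code paths at reduced scale — grid 40, 25 points
per class, 100 bootstrap iterations, 50-tree forests, 60-epoch encoders —
chosen for runtime, not tuned to outcomes; the full-scale settings remain
the documented defaults of the API.

## Known limitations

* No geospatial referencing: rasters are plain pixel grids with a
  text-based serialization (no GeoTIFF dependency exists in the target
  environment); coordinates are 0-based pixel indices.
* The CAE interprets the feature vector as a temporal sequence; it is not
  a spatial (2-D) convolutional model and cannot exploit image texture.
* The bootstrap evaluates one classifier family (random forests) only.
* Accuracy differences between methods are reported as CI overlap, not
  formal hypothesis tests.
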