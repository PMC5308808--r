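---
title: "Methods: hue-based street greenery assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hue-based street greenery assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenview)
```

## The index and its assumptions

The Green View Index treats visible greenery as a color phenomenon: an
image is converted from RGB to HSV, the hue channel (0–360°) is binned at
1° resolution into a distribution summing to 1, and the GVI is the summed
mass of the green range — 60° to 180° by default, which covers
yellow-greens through blue-greens. The model's assumptions are explicit and
deliberately simple:

- **Hue alone identifies vegetation.** No saturation or value gating is
  applied by default, so dark-green vehicles, signs and painted walls count
  as green, and heavily shadowed foliage still counts so long as its hue
  survives. Optional `min_saturation` / `min_value` arguments to
  `hue_histogram()` exist for sensitivity analysis only.
- **Achromatic pixels are non-green.** Gray, white and black pixels
  (saturation 0) have no defined hue; they are assigned hue 0 by convention
  and therefore never fall in the green range.
- **A site is the mean of its views.** Up to four directional images
  (front, back, left, right of the street direction) are averaged; when a
  provider returns fewer, the mean is over what exists (`min_images`
  guards the floor), and sites with no imagery are excluded and counted.

Site GVIs are classified on a four-level scale with thresholds 0.2, 0.4
and 0.5, applied as ≤ 0.2 / (0.2, 0.4] / (0.4, 0.5] / > 0.5.

## Numerical choices

- **Half-open hue ranges.** A green range `[lo, hi)` excludes bin `hi`, so
  adjacent ranges partition exactly and GVI is additive over subranges.
  Bounds are restricted to whole degrees; `picture_gvi()` then sums
  integer bin counts before dividing, making the histogram route
  bit-identical to per-pixel classification (a property the test suite
  asserts on a thousand random images).
- **Degrees everywhere.** R's `rgb2hsv()` returns hue in [0, 1]; it is
  rescaled to degrees before binning so the 60–180 range and the 360-bin
  histogram mean what they say.
- **Population standard deviation.** Segment-, block- and city-level
  spread divides by n, not n − 1; a `sample` flag flips this.
- **Strict density filters.** "Over 13 locations per km" and "over 1
  location per ha" are strict inequalities; a segment at exactly 13/km is
  dropped.
- **Tie-breaks.** A site equidistant from two blocks goes to the smaller
  block id; typology boundary ties go to the Low class on both axes. Both
  rules exist to make reruns deterministic, not because the boundaries are
  scientifically meaningful.

## Street-network preprocessing

Raw centerline data carry dual carriageways, dangling stubs and
pseudo-nodes that would distort sampling. The pipeline applies, in order:
class/bridge removal (highways and bridges are not walkable street space),
divided-road merging, topology enforcement, and study-area clipping.

- **"Generally parallel"** is operationalized as principal directions
  within 15° and symmetric vertex-to-polyline Hausdorff distance within the
  merge distance (default 30 m). Matched same-class pairs are replaced by
  the midline of perpendicular foot-point averages. These two knobs are
  configuration, not claims about any particular commercial toolchain; a
  reproduction of a specific dataset's segment counts is not claimed.
- **Topology.** Pseudo-nodes (degree-2 nodes joining two same-class
  segments deflecting ≤ 45°) are dissolved before dangle removal so a
  continuous street split mid-block is never mistaken for two short stubs;
  then degree-1 stubs shorter than the dangle threshold (default 100 m,
  a configuration choice the underlying data model leaves open) are
  removed; the two passes repeat to a fixed point. Total length is
  conserved by dissolution to 1e-6 m. Crossing streets are left unsplit.
- **Projection.** All metric operations require projected meters. Lon/lat
  input is reprojected with a spherical azimuthal-equidistant projection
  centered on the study area — exact in distance from the center, and with
  negligible distortion at the 3 km radius a downtown study area uses.
- **Sampling.** Sites sit at chainages 0, 50, 100, … m, so every segment
  gets `floor(L/50) + 1` sites and even a 40 m stub is represented by its
  start. The forward azimuth at a site is the direction of the polyline
  edge containing its chainage; at an exact vertex the following edge is
  used (the trailing edge for the terminal site). The four headings are
  azimuth + {0, 180, 90, 270}° labeled front/back/left/right.

## Block delineation

A block is the contiguous area left when street space — a buffer of
class-dependent half-width, linear from 30 m (highest class) to 2 m
(lowest) unless overridden — is removed from the study area. Delineation is
raster-based: cells within a segment's half-width are street space, free
cells are labeled into 4-connected components with a run-based union-find,
and components touching the study-area boundary are discarded because they
are not confined by streets. Area is cell count × cell area; boundary
polygons come from marching squares and are export/plot artifacts, while
nearest-block distances use boundary cell centers (deterministic and
symmetric on symmetric configurations). The default resolution targets
~2000 cells across the extent, clamped to [0.25, 4] m; on axis-aligned test
geometry with a snapped grid origin, areas are exact (the 200 m square
loop with a 5 m buffer yields one 3.61 ha block to machine precision). Two
degenerate cases follow the interface contract: an empty network returns
the whole study area as one block with a warning; a buffer wide enough to
swallow the interior returns zero blocks with a warning.

## City statistics

Cities are summarized by the mean and population SD of their site GVIs and
classified into four types against the cross-city average of the two
values. Spatial autocorrelation uses global Moran's I with row-standardized
k-nearest-neighbor weights (k = 8 by default; the weight structure is a
configuration choice since point summaries carry no intrinsic adjacency),
an analytic z-score under the normality assumption, and a 999-permutation
empirical null. The implementation is independent of `ape::Moran.I`, which
serves as a cross-check in the tests.

Location-level regressions z-score the response and every predictor, so
coefficients are standardized and comparable. Three nested models are
fixed: street attributes (CENTER, LENGTH); plus city controls (SIZE,
LEVEL, DENSITY, ECONOMY, ELEVATION, WATER); plus region dummies (MIDDLE,
WEST). LEVEL enters as a numeric ordinal because a single coefficient per
model is reported; the machinery accepts any data frame, so users who
prefer factor coding can pass dummies themselves. P-values are classical
OLS t-tests without clustering by default — sites within a city share
covariates, so a cluster-robust analysis would be a natural extension, and
the unclustered choice is the faithful baseline. Backward elimination
(within one administrative level, LEVEL and other zero-variance columns
dropped up front) removes the largest-p predictor until all remaining have
p ≤ 0.05.

One consequence of that stopping rule is worth stating plainly: with seven
truly null candidate predictors, each survives with probability ≈ 0.05, so
the chance that the final model equals the true predictor set exactly is
capped near 0.95⁷ ≈ 0.70 regardless of sample size. The test suite
therefore asserts what the procedure can deliver — true effects of
standardized magnitude ≥ 0.1 are retained essentially always, and the
false-inclusion count stays at the level the threshold implies — and
documents the exact-set ceiling with a deliberately strict companion check.

## What the synthetic generators emulate — and what they do not

- **Scenes** (`make_scene()`) place vegetation as coherent disk blobs
  (canopy-like patches, not salt-and-pepper noise) with hues inside a green
  band, against sky-, building- and road-like clutter. Illumination jitter
  multiplies the HSV value channel only, so quantifying brightness
  sensitivity never corrupts the hue ground truth; hues are sampled 4°
  inside band edges and the value channel is floored at 0.25 so 8-bit RGB
  quantization cannot move a pixel across a band boundary. The mask is
  exact: the target green fraction is met to within one pixel.
  Consequently hue-range GVI recovers the truth perfectly on these scenes —
  passing the synthetic benchmark shows the index arithmetic is right, not
  that hue classification is unbiased on photographs, where brown trunks,
  yellowed leaves, green paint and compression artifacts all bite.
- **Street grids** (`make_street_grid()`) produce rectangular lattices
  with controlled counts of dual carriageways, dangles and pseudo-node
  splits. Real networks are not lattices; the grid isolates each topology
  rule so its effect is countable.
- **Panels** (`make_city_panel()`) draw city covariates independently
  (log-normal sizes/economies/densities, tier probabilities weighted
  toward prefecture-level cities, a three-way region draw) and z-score
  them within the panel; the response is the standardized linear
  combination plus Gaussian noise. Fitted standardized coefficients
  estimate `beta / sd(y)`; generator-based tests set
  `noise_sd = sqrt(1 - sum(beta^2))` so `sd(y) = 1` and the targets are
  the betas themselves. Real covariates are correlated and effects are not
  linear; parameter-recovery results certify the estimator, not the urban
  science.

## Problem sizes and runtime choices

The test suite and acceptance script run at desk scale by design: scenes of
120–320 px width (the provider default remains 960 × 640, the size a live
panorama API delivers), grids of 9–20 nodes, block rasters of ≤ 1 M cells,
panels up to 50,000 rows, 999 permutations for Moran's I, and 50-seed
elimination studies. These sizes were chosen so each scientific property is
tested at the smallest scale where it is non-trivial.

## Known limitations

- Hue-only classification confounds any green object with vegetation and
  misses vegetation whose hue leaves the green range (autumn foliage,
  backlit canopy); semantic segmentation is out of scope.
- Shapefile input is not supported; street layers are read from GeoJSON.
- Raster block delineation approximates curved buffer geometry at the cell
  scale; holes in blocks (interior street islands) are not represented in
  the exported outer ring.
- The live provider implements the documented request dialect but is
  exercised only through its URL construction offline; coverage and image
  content of any real service change over time and are not reproducible.
- Timestamps are generally unavailable through panorama APIs, so seasonal
  screening of imagery (leaf-off winter scenes depress the index) must
  happen outside the package.
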