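---
title: "Extracting plot-level plant height from UAV photogrammetry surface models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting plot-level plant height from UAV photogrammetry surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavph)
```

## The problem

Plant height (PH) is a core trait in field phenotyping of row crops such
as maize. UAV structure-from-motion (SfM) photogrammetry turns overlapping
aerial images into a digital surface model (DSM): a raster of surface
elevation that includes the vegetation. Plot-level plant height is then
the difference between the canopy surface and the *ground* altitude

$$\mathrm{CHM} = \mathrm{DSM} - \mathrm{DTM},$$

where the crop height model (CHM) is evaluated per plot and the digital
terrain model (DTM) — the bare-ground altitude — is the quantity that has
to be estimated. This package implements and compares the three standard
strategies for obtaining it:

* **M1 — off-season differencing.** A DSM of the bare field (flown before
  germination) serves as the DTM and is subtracted from the on-season DSM
  of the same acquisition condition and repetition.
* **M2 — within-plot percentiles.** Inside each plot rectangle, the 2nd
  percentile of elevations is taken as the soil altitude and the 98th as
  the apex altitude; their difference is the plant height. No second
  flight is needed, but soil must be visible inside the plot.
* **M3 — polynomial terrain surface.** Bare ground is sampled in a ring
  of rectangles around the field (median elevation at each rectangle
  centroid), and a polynomial surface
  $$z = \sum_{k=0}^{n} \sum_{i=0}^{k} a_{ki}\, x^{k-i} y^{i}$$
  is fitted to the ring points by least squares and used as the DTM.

Row height is read from the CHM as the 98th percentile of the pixels in a
rectangle over the measured plants. The percentile band (98th/2nd rather
than max/min) makes the extraction robust to small blobs of spuriously
high points, a common SfM artifact: a blob of at most 2 % of an ROI's
pixels cannot displace the 98th percentile by more than one rank window.

Photogrammetric height `ph_sfm` systematically underestimates measured
height `ph_measured` because thin plant tops (leaf tips, tassels) are
attenuated in the reconstruction. A linear calibration

$$\mathrm{PH}_{measured} = a \cdot \mathrm{PH}_{SfM} + b$$

absorbs this, and the package evaluates it with a deliberately hard
cross-validation: *different-targets-and-different-flight* validation,
where the validation samples come from a held-out spatial group of the
field **and** from a different flight repetition than the training
samples. With 3 repetitions and 3 groups this gives
`nrow(enumerate_cv_sets(3, 3))` = 18 validation sets per condition. This
scheme is what separates methods that merely correlate well within one
flight from methods whose calibration transfers to new flights: each
reconstruction floats on its own vertical datum, and a calibration fitted
on one flight inherits that flight's datum in its intercept.

## Why a synthetic scene generator

The package is developed and tested against a generator that emulates the
statistical structure of SfM rasters over a maize variety trial, because
the interesting behavior of the three methods is driven by a small set of
mechanisms that the generator reproduces explicitly:

* **Terrain**: a gently tilted cubic ground surface (about 0.7 m of
  relief), plus smooth non-polynomial micro-relief (two sinusoid products,
  12 mm at 7 m wavelength and 10 mm at 1.7 m, with flight-specific random
  phases) standing for soil undulation and reconstruction ripple.
* **Doming**: a radially symmetric quadratic bulge centered on the
  region, the classic SfM distortion of nadir-only imagery. Amplitude
  0.15 m for a −90° camera, scaled by 0.25 for a −60° (diagonal) view,
  with 10 % flight-to-flight jitter. The bulge is applied to *every*
  simulated flight — it is an artifact of each reconstruction — so in M1
  it largely cancels between the paired flights.
* **Datum offsets**: each flight receives a vertical offset drawn with
  sd 0.5 m without RTK and 0.03 m with RTK (centimeter-grade positioning
  still leaves centimeter-level vertical error). The GCP flag zeroes the
  realized offset after rendering: ground control anchors the datum but
  changes nothing else.
* **Canopy**: one true height per row (plot-level variety effect plus row
  noise, each carrying half the variance, clipped to the stage's range;
  vegetative stage mean 0.898 m, sd 0.102 m; reproductive 2.68 m,
  sd 0.181 m). Crowns are flat-topped cones whose apex sits at the true
  height minus an *apex shrinkage* (0.08 m vegetative, 0.23 m
  reproductive) — the systematic negative bias the calibration must
  absorb. Where soil is not visible, the reconstructed surface closes
  over the inter-plant space at a row-specific random fraction
  (0.25–0.75) of plant height.
* **Soil visibility**: the fraction of within-row pixels left at ground
  level is 0.4 for young plants under a nadir view, scaled by 0.04 for a
  −60° view (wider apparent plant areas hide the soil), and 0.015 under a
  closed reproductive canopy. When the fraction falls below the 2 %
  exclusion band of the percentile method, M2's soil percentile climbs
  into the canopy and the method collapses — at the diagonal angle in the
  vegetative stage, and at both angles in the reproductive stage.
* **Noise**: per-pixel Gaussian noise (sd 0.01 m) and a few connected
  blobs of high pixels (≤ 12 pixels each at the default 0.03 m pixel,
  keeping each blob under 2 % of an ROI, mirroring the observed artifact
  scale relative to ROI size).

Offset magnitudes, doming amplitude, micro-relief, closure behavior and
the soil-visibility mapping are simulator *assumptions* chosen to be
realistic for low-altitude SfM over agricultural fields; they are not
measured values. What passing tests show is therefore that the *methods*
behave as the mechanisms dictate — datum sensitivity of M1, soil
dependence of M2, datum invariance and overfit hazard of M3 — not that
any particular field would produce the same metric values. Real SfM
rasters additionally contain spatially correlated reconstruction error,
motion blur, shadows and georeferencing drift that the generator does not
model.

## Field geometry

The emulated trial plants plots of 4 rows × 18 plants at 0.75 m row
spacing and 0.18 m in-row spacing (7.41 plants/m²). Height is measured in
the middle two rows of each plot; the mean over 5 consecutive plants in a
row is one sample. The full-scale calibration field
(`field2_layout_fullscale()`) has 84 plots in a 35.5 m × 54 m region —
168 samples in three contiguous spatial groups of 56, so each validation
set trains on 112 samples and validates on 56. Each row is split into
three blocks; the central block holds the measured plants, and one inner
ROI (0.75 m wide, spanning the block's plants plus half a plant spacing
at each end) is built per row and block.

```{r layout}
f2 <- field2_layout_fullscale()
n_measured_rows(f2)
planting_density(f2)
nrow(build_inner_rois(f2))
```

The bare-ground ring (`build_outer_rois()`) tiles the field perimeter
just outside the region boundary: nominal 1 m × 0.5 m rectangles along
the sides (the last piece of a side shortened to fit) and 0.5 m × 0.5 m
squares diagonally off the corners. The tiling is gap-free and never
intrudes into the region.

## Numerical choices

* **Coordinate conditioning.** Surface fitting centers and scales x and y
  to about [−1, 1] before building the monomial basis. Raw field-scale
  coordinates make the degree-3/4 normal equations numerically singular.
* **Rank checking.** `fit_polynomial_dtm()` fails loudly on rank-deficient
  designs instead of returning a minimum-norm solution. This matters in a
  non-obvious way: the centroids of an *exactly* tiled rectangular ring
  lie on four lines, so the quartic $(x-x_1)(x-x_2)(y-y_1)(y-y_2)$
  vanishes at every sample point and a degree-4 fit is exactly
  unidentifiable. Hand-digitized ring ROIs are slightly irregular; the
  generator emulates this with an optional placement jitter (sd 0.02 m),
  which makes degree 4 barely identifiable — and therefore wildly
  noise-amplified in the field interior. This is the mechanism behind the
  degree-4 overfit that degree selection must avoid.
* **Degree selection** (`select_degree()`) averages the per-repetition
  correlation between measured and photogrammetric height for each
  candidate degree and takes the argmax, breaking ties toward the lowest
  degree. On the cubic-terrain reference preset the procedure selects
  degree 3, with the degree-4 mean correlation lower (the acceptance
  suite computes this).
* **Percentiles** interpolate linearly between order statistics
  (`quantile type 7`: rank position $q/100 \cdot (N-1)$).
* **Pixel membership** is center-in-rectangle, half-open on the max
  edges, so adjacent ROIs never share a pixel.
* **Median aggregation bias.** The ring sample's z is the ROI *median*.
  Over planar terrain with ROI edges aligned to the pixel grid the pixel
  set is symmetric and the median equals the surface at the centroid, so
  M3 recovery is exact (the suite checks 1e-6). Over curved terrain, or
  with sub-pixel ROI placement, the median is not the centroid value,
  which bounds recovery at millimeter level (checked at 2e-3) — an
  inherent property of median zonal sampling, not a solver tolerance.
* **Nodata** is tolerated up to 50 % of an ROI and excluded from
  statistics; beyond that the extraction fails loudly.
* **R² on validation** uses the validation set's own mean in the total
  sum of squares and is not clipped below zero — a calibration carried to
  a flight on a different datum can and should score far below zero.
* **MAPE** is `100 * mean(|error| / measured)`.
* **Determinism.** Every stochastic element (heights, flights, jitter)
  derives its seed from a single master seed; identical configurations
  give byte-identical CSV products.

## The simulated study preset

`replicate_study_structure()` reproduces the organization of a two-field
study at desk scale: degree selection on a 12-plot reference field
(24 samples, nadir flights, 3 repetitions, candidate degrees 0–4), then a
24-condition comparison (2 camera angles × RTK × GCP × 3 methods) on an
18-plot calibration field (36 samples, groups of 12, each validation set
training on 24 and validating on 12) at 0.03 m pixels. These sizes keep a
full run in the tens of seconds; the full-scale 84-plot geometry is used
for the design counts and the n = 112 calibration-recovery check. The
run's per-stage condition tables are ranked by validation R² and label
the two reference conditions: **LC** (low-cost: −60°, no RTK, no GCP,
M3) and **HC** (highest-cost: −60°, RTK, GCP, M1).

```{r replicate, eval = FALSE}
res <- replicate_study_structure(seed = 1)
res$selected_degrees
head(res$field2$vegetative$stages$vegetative$table)
```

The test suite asserts the qualitative structure this produces: M3
transfers across flights under every datum condition including LC; M1
without GCP shows high within-flight correlation but large per-flight
bias and strongly negative validation R², recovering only with ground
control; M2 collapses exactly when soil visibility drops below the
percentile exclusion band.

## Known limitations

* Rectangular, axis-aligned ROIs only; ROIs are defined in field
  coordinates, not digitized on imagery.
* The generator does not model photogrammetric reconstruction itself:
  no image rendering, no GNSS error structure beyond scalar offsets, no
  weather or illumination effects, no horizontal misregistration.
* Ring sampling assumes visible bare soil around the field; a field
  without margins would need M1 with datum support instead of M3.
* Rasters are serialized as ESRI ASCII grids (plain text, explicit
  nodata); there is no compressed/geotagged binary raster support.
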