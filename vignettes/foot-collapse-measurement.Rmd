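---
title: "Measuring foot collapse on lateral weight-bearing radiographs"
author: "footmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring foot collapse on lateral weight-bearing radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footmark)
```

## The measurement problem

Progressive collapse of the longitudinal arch — most commonly from Charcot
neuroarthropathy in diabetic patients — is monitored on lateral
weight-bearing foot radiographs with three standard measurements:

* **Calcaneal tilt (CT, degrees)** — the inclination of the calcaneus against
  its support construction; it decreases as the arch flattens.
* **Cuboid height (CH, mm)** — how far the inferior cuboid outline sits above
  the line joining the inferior calcaneus to the base of the fifth
  metatarsal; it decreases, and can go negative, in rocker-bottom collapse.
* **Meary's angle (MA, degrees)** — the angle between the talar axis and the
  first-metatarsal axis; near 0 in a normal arch and increasing with midfoot
  collapse. The widely used grading applies thresholds to the magnitude:
  normal if $|MA| \le 4$, mild if $4 < |MA| < 15$, moderate if
  $15 \le |MA| \le 30$, severe if $|MA| > 30$.

Taking these measurements by hand is slow and shows appreciable
inter-observer variability, which motivates a fully automatic pipeline: a
landmark localizer that outlines the bones of interest with 61 ordered
points, and a geometry calculator that derives CT, CH and MA from those
points alone.

## The 61-point model and the geometry calculator

All computation is index-driven through a fixed landmark scheme
(`footScheme()`). Coordinates are image coordinates: x = column, y = row,
origin top-left, so "superior" means smaller y. Annotations of either
laterality are canonicalized (toes toward +x) by mirroring before
measurement; the mirroring is an involution, so measurements of a flipped
radiograph match the original exactly.

The three measurements are built from splines and lines over specific
indices:

* CT is the unsigned angle at point 10 between the rays to points 11 and 12,
  reduced to $[0, 90]$.
* CH is the minimum signed perpendicular distance between the infinite line
  through points 13 and 15 and a piecewise cubic spline through points
  37-38-39-14-40-41-42, converted to mm with the pixel spacing. The sign is
  positive while the cuboid outline is superior to the baseline and negative
  once it crosses inferiorly; a signed value keeps rocker-bottom collapse on
  a continuous scale. The baseline is treated as an infinite line rather
  than a segment, since the construction measures a height, not a distance
  to a bounded object.
* MA is the signed angle from the talar axis to the metatarsal axis, in
  $(-90, 90]$, positive when the metatarsal axis deviates inferiorly. The
  metatarsal axis is the centre line between splines through points 20–24
  and 25–28: both are sampled at matched normalized arc-length fractions
  (200 samples), and a total-least-squares line through the midpoints gives
  the axis. The talar axis joins the midpoint of points 4–5 with the
  midpoint of point 9 and the most superior point of the spline through
  points 8-16-17-7-18-19-6.

Splines are interpolating natural cubics with chord-length parameterization.
Extrema on curves (the most superior talar point, the closest cuboid
approach) are found by dense sampling (1000 points) followed by root finding
on the analytic spline derivative, which pins the extremum to machine
precision; that is what makes the rigid-motion invariance tests pass at the
$10^{-9}$ level rather than at the tolerance of a golden-section search.

Two conventions deserve comment because the construction itself does not fix
them:

* **"Most superior" is measured against the weight-bearing baseline**
  (points 13→15), not against raw image rows. On an upright radiograph the
  two coincide; defining it this way makes the whole measurement invariant
  under in-plane rotation of the image, which raw argmin-y is not.
* **MA is reported signed** by default (an `unsigned` mode is provided).
  Manual Meary's angles are conventionally magnitudes, but the large spread
  of manual measurements across collapse cohorts spans negative values, and
  a signed angle is what the severity grading's magnitude thresholds are
  applied to (`classifyMearys()` grades $|MA|$ by default, with a `raw`
  mode for pipelines that already carry magnitudes).

Boundary values in the grading follow the threshold chain literally: 4 is
normal, 15 and 30 are moderate.

```{r measure-template}
tm <- footTemplate()
round(measureAll(tm), 2)
classifyMearys(measureAll(tm)[["ma_deg"]])
```

Pixel spacing comes from the DICOM header (PixelSpacing, with
ImagerPixelSpacing as fallback) via a minimal little-endian DICOM element
walker; files with anisotropic spacing (row vs column differing by 1% or
more) are rejected rather than silently averaged, because the angles are
computed in pixel space and are only meaningful under isotropy.

## The synthetic study

The clinical images behind this kind of system cannot be redistributed, so
the package carries a synthetic test bed that emulates the *structure* of a
podiatry cohort and closes the loop between generator, geometry and
statistics.

**Template and deformations.** `footTemplate()` is a canonical normal foot
(CT ≈ 18°, CH ≈ 19.9 mm, MA ≈ −0.5° at 0.15 mm/px) whose 61 points are
consistent with the scheme's bone outlines. `deformTemplate()` induces
disease geometrically: the first-metatarsal block rotates about its proximal
base until MA hits its target exactly (1-D root finding), the calcaneal ramp
block rotates about point 10 to set CT, and the cuboid block translates
vertically to set CH. The three blocks are disjoint from each other's
measurement landmarks, so the solves are independent and the generator's
labels are exact by construction — which is what lets the generator serve as
an oracle for the geometry, the severity grading and the statistics at once.
A rigid pose (rotation, translation, scale with compensating pixel spacing)
is applied last and provably changes nothing.

**Cohort structure.** `cohortSpec()` defaults emulate a retrospective
clinical cohort: 79 subjects carrying 1–13 images each (median 2, IQR 1–3),
an image-level severity mix of 69:68:34:17
(normal:mild:moderate:severe), and per-image pixel spacing drawn from
0.45–0.55 mm/px. Severity classes are packed onto subjects greedily
(largest remaining image deficit first) so the image-level mix is met within
rounding. Each subject has a base deformation shared by its images plus a
linear per-image progression drift, clamped to the subject's class interval
— repeated imaging of one foot over time, in caricature. Within-class
parameter choices are fixed design: MA targets are uniform on
(−3.5, 3.8), (4.6, 14.4), (15.3, 29.7) and (30.5, 42) for the four classes
(kept strictly inside the grading boundaries so root-finder tolerance cannot
flip a label; normal feet legitimately include mildly negative angles), and
calcaneal-tilt / cuboid-height deltas shift downward with severity with SDs
chosen to reproduce the overall spreads reported for such cohorts (CT SD
around 6–7°, CH SD around 6 mm across all classes).

**Observer panels.** Five simulated experts report
truth + observer offset + noise per measurement. Offsets are drawn once per
observer per cohort with SDs $\sqrt{2.4}$°, $\sqrt{3.6}$ mm and
$\sqrt{6.6}$° for CT/CH/MA — the square roots of realistic inter-observer
variances for these measurements — and within-observer noise SDs are 2.0°,
2.0 mm and 3.5° (plausible values; published tables report the
between-observer components but not the residuals). A missingness rate
exercises the exclusion rule.

**Rendering.** `renderRadiograph()` draws filled bone polygons with
brighter cortical rims on a soft-tissue gradient, then Gaussian blur and
additive noise. It is deliberately schematic — enough appearance structure
for a localizer to learn from, with none of the bone fragmentation texture
of advanced Charcot disease. Conclusions about the localizer therefore
transfer to real radiographs only qualitatively; conclusions about the
geometry calculator and the statistics do not depend on the rendering at
all.

## The landmark localizer

The point-finder is a shape-constrained regression-voting localizer, a
compact stand-in for the full random-forest regression-voting constrained
local model family:

* a PCA shape model over Procrustes-aligned training shapes (modes retained
  to 99.8% of variance, coefficients clamped at ±3 SD);
* per landmark and per resolution stage (downscale factors 4, 2, 1), two
  random-forest regressors (14 trees) predicting the (dx, dy) displacement
  from a 7×7 normalized intensity patch (bilinearly sampled, optionally at
  wider spacing for more context) to the landmark, trained at random
  displacements within the stage's search range, with three augmentation
  replicates per image (patch-grid rotation ±15°, scale ±10%);
* at search time, a Hough-style translation vote followed by a grid search
  over the two leading shape modes initializes the shape, then each stage
  alternates regression voting with regularization. Votes are reduced to
  their densest cluster; the cluster's 2×2 covariance records per-direction
  reliability (an edge landmark is precise across the edge but smeared along
  it). The update blends, per landmark and per direction, the voted
  position with a robust anisotropic shape-model fit, so reliable vote
  directions lead while ambiguous ones follow the shape prior. Two
  unconstrained confidence-blended refinement passes finish the fine stage.

The blended update matters: a pure shape-fit iteration systematically drags
the long, locally ambiguous first-metatarsal shaft toward the training-mean
configuration, which biases Meary's angle by several degrees exactly in the
clinically interesting near-normal range. The per-direction blend removes
that bias while keeping the shape constraint for genuinely ambiguous
landmarks. All search and training randomness is seeded; a localization call
is deterministic and a saved/reloaded model predicts identically.

Cross-validation (`crossvalPointFinder()`, `assignFolds()`) is grouped by
subject: folds are built by seeded greedy packing (shuffle subjects, assign
each with all its images to the smallest fold), so no subject ever appears
in both training and test of a fold and fold image counts are balanced
within the largest per-subject image count.

## The statistics suite

All panel statistics require a complete image × observer table; the
exclusion rule (`filterComplete()`) first drops every image for which any
observer missed any measurement, mirroring how unmeasurable radiographs are
handled in practice.

* **ICC(2,1)** (`icc2Panel()`): intraclass correlation from the two-way
  random-effects ANOVA with images and observers both random, single rater,
  absolute agreement — the standard reading of "ICC type 2". Variance
  components by method of moments (inter-image IIV = (MSR−MSE)/k,
  inter-observer IOV = (MSC−MSE)/n, residual = MSE, negatives truncated at
  zero), plus the observers' proportion of variance
  POV = IOV/(IOV+IIV+residual). The 95% CI uses the F-distribution method,
  with a cluster bootstrap over images as an alternative. Method-of-moments
  is exact for the balanced complete tables the exclusion rule guarantees;
  tests cross-check it against an REML mixed-model fit.
* **Bias** (`biasModel()`): the two-way random-effects model on the per-cell
  differences derived − manual; for balanced complete data the estimate is
  the grand mean of differences (asserted as an exact identity in tests).
  The Wald statistic uses the method-of-moments variance of the mean,
  Var = (MSR+MSC−MSE)/(nk), referred to a t distribution with Satterthwaite
  degrees of freedom. With only five observers the observer component has
  ~4 effective degrees of freedom, and a normal reference would roughly
  double the nominal type-I error; the Satterthwaite t keeps the simulated
  type-I rate near 5%.
* **PCC** (`pccBootstrap()`): Pearson correlation between derived and manual
  values, CI by percentile bootstrap with 1000 repeats resampling *images*
  (clusters), respecting the repeated-measures structure. Whether "manual"
  means the per-image observer mean or all observer pairs is not fixed by
  convention, so both pairings are implemented; the per-image mean is the
  default.
* **Within range** (`withinRange()`): the percentage of images whose derived
  value lies inside [min, max] of the observers' values, boundaries
  inclusive.
* **Landmark errors**: the point-to-point error is the mean over the 61
  per-landmark distances in mm; the point-to-curve error replaces each
  distance by the distance to the nearest point of the spline through the
  ground-truth points of that landmark's bone group, which forgives
  tangential slippage along an outline. One curve per bone group (rather
  than one global curve) is the reading that matches how the outlines are
  annotated; landmarks outside any group, or in groups of fewer than three
  points, fall back to point-to-point. `errorCdf()` summarizes per-image
  errors as an empirical CDF with quantiles and threshold fractions.

Severity stratification of the comparison statistics uses the mean manual
Meary's angle per image, graded with the standard thresholds.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full loop at sizes chosen
to keep a complete run on one CPU comfortable: the end-to-end study
simulates a cohort of 37 subjects (about a hundred images at the default
images-per-subject distribution), renders at 0.45–0.55 mm/px (foot spans
roughly 300×160 px), and runs 10-fold subject-grouped cross-validation;
statistical calibration uses 188-image panels with 200 recovery replicates
and 500 null replicates for the bias test. Dense curve searches use 1000
samples plus derivative root finding (tolerance 1e-14 in the curve
parameter); brute-force oracles in tests use $10^5$ samples. Degenerate
geometry (coincident construction points, zero-variance panels, blank
images) raises classed errors rather than returning numbers; batch pipeline
runs flag per-image failures and continue.

## Known limitations

* The localizer is trained and validated on schematic renderings; absolute
  accuracies (fractions of a mm here) say nothing about clinical accuracy on
  real radiographs, where bone fragmentation and overlap dominate. The rank
  structure — degradation with severity, the metatarsal axis being the
  fragile construction — is the transferable observation.
* The severity grading carries only the Meary's-angle-based labels; a
  clinical-review grade is a human judgement with no algorithm and is
  represented, at most, as a label field on synthetic data.
* The DICOM support reads the pixel array and spacing tags of little-endian
  files and writes minimal 8-bit secondary captures; it is not a general
  DICOM implementation.
* Localization equivariance under image translation is exact only to about
  a pixel, limited by the discretized coarse search grids.
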