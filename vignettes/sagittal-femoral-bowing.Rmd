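---
title: "Measuring sagittal femoral bowing from canal centroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sagittal femoral bowing from canal centroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femcurve)
```

## The measurement

Sagittal femoral bowing (SFB) is the anterior curvature (procurvatum) of the
femoral shaft seen from the side. `femcurve` quantifies it as a radius of
curvature: the radius of the unique circle through three medullary-canal
centroids taken 5 cm apart, projected to the sagittal plane. A larger radius
means a straighter bone; a *decrease* in radius over time means the bow has
tightened.

The procedure, end to end:

1. **Standard orientation.** The femur volume is rotated so that one plane is
   simultaneously tangent to the most posterior points of both femoral
   condyles and of the greater trochanter; that plane becomes `y = const`
   with the bone anterior of it. The residual rotation about the plane
   normal is fixed by aligning the inter-condylar direction with the
   medio-lateral axis (the "both condyles overlap in the lateral view"
   condition). After orientation, x is medio-lateral, y antero-posterior
   (anterior positive) and z inferior-superior.
2. **Reference axial plane.** `z = 0` is placed at the lowest margin of the
   two condyles; every level height is measured from it.
3. **Level centroids.** The canal label is sampled at seven axial levels,
   5–35 cm in 5 cm steps. Each level mask is cleaned to its largest
   connected component and its centroid (area-weighted mean of voxel
   centres) becomes one centreline point.
4. **Segment radii.** Circumcircles through the canonical triplets give the
   per-segment radii: distal 5/10/15 cm, middle 15/20/25 cm, proximal
   25/30/35 cm, whole femur 5/20/35 cm.
5. **Paired change analysis.** For a patient with baseline and follow-up
   scans, the change `delta = R_post − R_pre` is computed per segment on the
   treated femur (`delta_P`) and on the untreated contralateral femur
   (`delta_C`); the two are compared across patients with the two-sided
   Wilcoxon signed-rank test at `alpha = 0.05`, after an inter-observer
   reliability screen and a baseline treated-vs-control symmetry check.

Femurs are screened before analysis: a reversed (posterior) whole-femur bow
direction excludes the femur as dysmorphic, and the segment length from the
inferior border of the lesser trochanter to the transepicondylar axis must
lie in the inclusive window 35–40 cm (the exclusion rule is strictly
"< 35 cm or > 40 cm").

## The circle fit

Three non-aligned points determine exactly one circle. The implementation
intersects the two perpendicular bisectors in closed form; this is
algebraically equivalent to the slope-form centre equations (slopes of the
two chords) but has no singularity for vertical or horizontal chords. A test
cross-checks the first centre coordinate against the slope form where the
slopes are defined, and the whole fit against an independent
perpendicular-bisector solver on 10^4 random triplets.

Collinearity is judged on the *normalised* triangle — coordinates divided by
the longest chord — so the behaviour is scale-free: normalised area below
1e-9 yields a degenerate fit with `R = Inf` and no direction, never a crash.
Physiological geometry is far from this threshold (a 1 m radius measured on
points 100 mm apart has normalised area ≈ 0.006). Coincident points are an
error. The radius is reported unsigned with a separate anterior/posterior
direction flag; the exclusion rule reads the flag, and the delta arithmetic
stays simple.

## Error model: why the slab and the tilted phantoms

The three-point fit amplifies centroid noise strongly. For a triplet
spanning `L = 100` mm, the sagitta of an arc of radius `R` is
`s ≈ L²/(8R)` — only 1.25 mm at `R = 1000` mm — so a perturbation `δ` of
one centroid propagates to `δR ≈ 8R²/L² · δ` (≈ 800·δ at 1 m). Two design
choices in this package follow directly from that number:

* **Level slab.** A centroid computed from a single 1 mm voxel slice of a
  binary mask carries ~0.05–0.08 mm of rasterisation noise, i.e. 4–6 %
  radius error — useless for per-segment work. `extract_level()` therefore
  averages a thin slab (default `slab_mm = 9`) centred on the level. A 9 mm
  slab is still thin against the 50 mm level spacing, and because a constant
  antero-posterior offset of all three triplet points leaves the
  circumradius unchanged, the slab's curvature-induced bias cancels exactly
  for a constant-curvature centreline. Single-slice behaviour is available
  by setting `slab_mm` to the slice thickness.
* **Acquisition tilt in the generator.** Rasterisation noise is strongly
  correlated between adjacent slices when the tube axis is aligned with the
  grid (the cross-section centre moves by only a few hundredths of a voxel
  per slice), so slab averaging alone does not help on a perfectly aligned
  phantom. Real patients never lie with the femoral shaft parallel to the
  scanner axis; `generate_phantom()` accordingly draws a seeded acquisition
  pose (rotations up to ±12° about the ML and AP axes, plus a sub-voxel
  grid offset). Oblique slabs intersect many grid layers, the quantisation
  error decorrelates, and the slab average converges. `standard_pose =
  TRUE` disables the tilt for exact fixed-point tests.

With both in place, the per-level centroid uncertainty at 1 mm voxels is
about 0.02–0.03 mm, and per-segment radius errors on the phantom grid
(R = 600–2000 mm) have a pooled median below 2 %, shrinking monotonically at
2 → 1 → 0.5 mm spacing — exactly what the acceptance suite measures. Note
what this does *not* show: each individual segment at the largest radii can
still deviate by several percent at 1 mm voxels; whole-femur (total) fits,
whose span triples `L`, are an order of magnitude more precise.

`apply_rigid_misalignment()` resamples labels nearest-neighbour. Its output
grid is at half the input pitch by default (`supersample = 2`): same-pitch
nearest-neighbour resampling re-quantises the frozen label boundary a second
time, and a convergence study (same transform at pitch 1, 1/2, 1/3) shows
that this double quantisation, not the orientation fit (which recovers known
rotations to better than 0.3°), dominates the radii differences. Even at
half pitch, re-orientation after a 10–30° misalignment reproduces segment
radii only to about 1–2.5 % at `R = 900` mm; small single-axis rotations are
the worst case because the nearest-neighbour moiré pattern then has a long
spatial period comparable to the slab.

## The synthetic generator as study twin

`generate_phantom()` builds the canal as a tube swept along a piecewise
circular arc in the sagittal plane: three arcs (distal, middle, proximal)
joined C¹-continuously at the 15 and 25 cm junction heights, apex at 20 cm.
Constant-curvature arcs are the natural ground truth because the measurement
itself is a three-point circle: each canonical triplet lies entirely on one
arc, so the generating radius is recovered *exactly* in the continuum limit.
The canal diameter profile tapers from a wide distal metaphysis (26 mm) to
an isthmus of 11 mm near 17–18 cm and flares proximally to 24 mm, matching
reported adult endosteal dimensions. Landmarks are spheres whose posterior
surfaces touch the `y = 0` plane, so the generating pose *is* the standard
configuration and the orientation fit has a known answer.

`generate_pair()` produces baseline and follow-up phantoms: the follow-up
re-bends the proximal (optionally middle) arc by a stated `ΔR` while leaving
the rest of the centreline untouched, and can erode the lumen into a
posterior crescent at chosen levels — the label-mask analogue of the
segmentation artifact around a cementless stem. Pre and post are rasterised
as independent acquisitions (fresh pose and grid), as two CT sessions would
be; consequently a measured `ΔR` carries the discretisation noise of two
scans (≈ 25–30 mm SD at `R = 900`, 1 mm voxels), and delta recovery is
assessed by regression slope across pairs rather than per-pair bands.

`generate_cohort()` scales this to a paired study (default n = 10 patients,
treated and control sides, two timepoints, two observers). At the default
centroid-table scale the level centroids are computed analytically from the
arcs and perturbed by two seeded uniform jitters: a scan-level component
(half-width `scan_noise_mm = 0.03`) shared by both observers of one scan,
and an independent per-observer component (`observer_noise_mm = 0.02`).
These half-widths equal the per-level centroid uncertainty of the 1 mm voxel
route, so the two output scales of the generator are mutually consistent;
propagated through the fit they give a within-pair radius noise of roughly
20 mm SD at `R = 1000` mm. The default treated-side proximal effect is
−60 mm (bow tightening) with null middle and control effects and a
between-patient baseline SD of 120 mm. Under these conditions the paired
proximal comparison at n = 10 is significant in well over 90 % of seeds
while the middle segment rejects at about the nominal 5 % — the
qualitative significant-proximal / null-middle pattern the design is meant
to detect. Effect magnitudes are free parameters of the simulator, not
claims about the clinical effect size. At the voxel output scale observer
noise becomes a seeded directional boundary erosion of each level mask
(depth uniform in `[0, observer_noise_mm]`), mimicking an observer tracing
slightly inside the boundary on one side; the erosion construction bounds
the centroid displacement by the noise amplitude.

What passing tests on these phantoms show — and what they do not: they
validate the geometry, the estimator chain, the statistics and their
interaction under a known, idealised truth. Real canals are not circular
tubes, real segmentations have texture- and observer-dependent biases that
are not zero-mean jitter, and metal artifacts distort more than the lumen
silhouette. Results on phantoms bound the method's best-case behaviour.

## Statistical choices

The Wilcoxon signed-rank statistic is the sum of positive-signed ranks `V`.
The exact null distribution is used for up to 25 informative pairs with no
ties and no zeros; otherwise a normal approximation with tie correction and
continuity correction. Zero differences follow the Pratt rule by default
(zeros are ranked, then their ranks are discarded, with the null moments
reduced accordingly), which is well defined at the study's n = 10;
`zero_method = "wilcox"` reproduces the drop-zeros convention. All paired
comparisons — inter-observer, baseline symmetry, and the headline
`delta_P` vs `delta_C` test — use the same routine; the package treats the
"Wilcoxon test for paired data" and the "Wilcoxon signed-rank test" as the
same procedure. No multiple-testing correction is applied across segments,
matching the study design the package mirrors; fewer than five comparable
pairs flags a result low-power, and a segment with fewer than five
inter-observer pairs is excluded as indeterminate rather than trusted.

The reliability screen is declarative rather than a hard-coded exclusion
list: any segment on which the two observers differ significantly is
dropped from downstream analysis, so a cohort whose distal measurements
happen to be reliable keeps them.

## Numerical conventions and degenerate inputs

* Physical units are mm internally; level heights are cm at the API surface
  and converted once.
* Slab selection is a half-open interval `|z − target| ≤ slab/2` on voxel
  centres; the centroid's z is the mean height of the slab voxels, which
  keeps the point on the centreline arc.
* Connected-component cleaning uses 4-connectivity within a single-slice
  mask and 26-connectivity for oblique multi-layer slabs; ties between
  equal-sized components resolve to the first in scan order.
* A crescent-shaped mask is detected by solidity (grid-quantised footprint
  area over convex-hull area, threshold 0.9) and flagged
  `artifact_cleaned`; an empty slab yields a `missing` level, and segments
  touching a missing level report not-computable instead of guessing.
* The tangency fit iterates support-point extraction and frame refitting to
  0.01° (max 50 iterations); support points are centroids of the voxels
  within half a voxel of the regional posterior extreme, which is robust to
  voxelisation. Three support points within 1 mm of a common line are
  rejected as degenerate.
* The eligibility window is inclusive at both boundaries. The
  transepicondylar axis is reduced to the segment joining the epicondyle
  region centroids; the inferior border of the lesser trochanter to the
  region's minimum-z voxel.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` run entirely on synthetic data
generated at run time: a radius grid {600, 900, 1200, 2000} mm at 1 mm
voxels, a spacing sweep {2, 1, 0.5} mm at R = 900, misalignments of 10° and
30° (compound), 20–40 pre/post pairs for delta recovery, 10^4 Monte-Carlo
null cohorts for the test's type-I error, and 100–200 seeded cohorts of 10
patients for the end-to-end power pattern. These sizes give Monte-Carlo
standard errors comfortably below the asserted margins while keeping a full
run in the minutes range on one CPU.

## Known limitations

* The sagittal projection is assumed before the fit (no 3-D circle fit);
  with the standard orientation this is the plane in which SFB is defined.
* Whether level centroids should come from one slice or a thin slab is not
  observable from the method description the package follows; the slab is
  the package's choice, for the noise reasons above, and is configurable.
* No metal-artifact modelling beyond lumen-silhouette erosion; no automatic
  segmentation; no coronal-bowing analysis (the generator can bow coronally,
  but no coronal statistics are provided).
* The NN-resampling invariance figures above are specific to label images;
  grayscale resampling follows different error laws.
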