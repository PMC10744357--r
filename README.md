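# femcurve

Sagittal femoral bowing (SFB) — the anterior curvature of the femoral shaft
seen from the side — changes after cementless total hip arthroplasty, and
measuring that change from CT requires a reproducible geometric pipeline.
`femcurve` implements one for R users working with labelled CT volumes of
the femur: standardized 3D orientation, medullary-canal centroid extraction
at fixed axial levels, per-segment radius-of-curvature estimation, and the
paired nonparametric comparison of prosthetic against untreated femurs. A
synthetic femur-phantom generator with known ground-truth curvature makes
every stage testable without any imaging data.

## The measurement

After rigidly orienting the femur (a plane tangent to the most posterior
points of both condyles and the greater trochanter becomes the vertical
reference; the reference axial plane sits at the lowest condyle margin),
the canal centroid c(z) is extracted at heights z = 5, 10, …, 35 cm. Each
femoral segment is summarized by the radius R of the circumcircle through
three centroids projected to the sagittal (y, z) plane:

- distal: 5 / 10 / 15 cm  ·  middle: 15 / 20 / 25 cm  ·
  proximal: 25 / 30 / 35 cm  ·  whole femur: 5 / 20 / 35 cm

with circumcentre (y_C, z_C) from the perpendicular-bisector equations and
R = ‖c₁ − (y_C, z_C)‖. Larger R = straighter bone. For a patient with two
scans, ΔR_P = R_P,post − R_P,pre on the prosthetic femur is paired with
ΔR_C on the untreated contralateral femur, and ΔR_P vs ΔR_C is tested per
segment with the two-sided Wilcoxon signed-rank test (α = 0.05), after an
inter-observer reliability screen that drops segments on which two
independent observers disagree.

## Worked example

Generate a 1 mm phantom whose canal follows a 900 mm sagittal arc, and
measure it end to end:

```r
library(femcurve)

spec <- phantom_spec(sagittal_radius_mm = 900, seed = 5)
vol  <- generate_phantom(spec)
res  <- measure_femur(vol, patient_id = "P01")
res$radii
#> Segment radii: P01 treated pre (observer obs1)
#>   distal   Circle fit: R = 902.12 mm, anterior bow, centre (y,z) = ( -856.986 , 200.794 )
#>   middle   Circle fit: R = 897.792 mm, anterior bow, centre (y,z) = ( -852.669 , 200.483 )
#>   proximal Circle fit: R = 881.212 mm, anterior bow, centre (y,z) = ( -836.171 , 202.443 )
#>   total    Circle fit: R = 898.96 mm, anterior bow, centre (y,z) = ( -853.836 , 200.465 )
```

All four segments recover the generating 900 mm radius (to ~2 % for the
100 mm-span segments, ~0.1 % for the whole femur), the bow is correctly
anterior, and the phantom passes the 35–40 cm eligibility window.

A full synthetic study twin — 10 patients, treated and control femurs, two
timepoints, two observers, a −60 mm proximal effect on the treated side
only:

```r
cohort   <- generate_cohort(phantom_spec(sagittal_radius_mm = 1000, seed = 1),
                            cohort_spec(n_patients = 10, seed = 2))
analyze_cohort(cohort)
#> Paired cohort analysis (alpha = 0.05 )
#>   inter-observer screen:  (all four segments reliable, p = 0.20 - 0.93)
#>   baseline comparison [proximal]: n = 10, V = 25, p = 0.8457 (not significant)
#>   delta comparison    [proximal]: n = 10, V = 1,  p = 0.003906 (significant)
#>   delta comparison    [middle]:   n = 10, V = 25, p = 0.8457 (not significant)
```

The treated-side proximal change is detected (p < 0.005) while baselines
are symmetric and the unchanged middle segment stays null — the
significant-proximal / null-middle pattern this study design is built to
resolve.

Real data enter through `read_volume("femur.nii.gz", "labels.yaml")` (NIfTI
or NRRD label masks plus a role→label mapping) or as centroid tables via
`read_centroids()`; `radii_table()`, `compute_deltas()` and
`analyze_cohort()` take it from there.

## Tests

```r
devtools::test()          # unit + property + acceptance suites, ~10 min
```

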