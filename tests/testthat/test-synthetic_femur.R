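test_that("phantom generation is deterministic given spec and seed", {
  a <- generate_phantom(phantom_spec(voxel_mm = 2, seed = 9))
  b <- generate_phantom(phantom_spec(voxel_mm = 2, seed = 9))
  expect_identical(a$voxels, b$voxels)
  expect_identical(a$origin, b$origin)
  c_ <- generate_phantom(phantom_spec(voxel_mm = 2, seed = 10))
  expect_false(identical(a$voxels, c_$voxels))
})

test_that("generated phantoms carry all declared landmark labels", {
  vol <- quick_phantom()
  for (role in names(vol$label_map))
    expect_gt(femcurve:::label_count(vol, role), 0)
})

test_that("unrealizable geometry errors before voxelisation", {
  expect_error(phantom_spec(sagittal_radius_mm = 150), "realizable")
  expect_error(phantom_spec(femur_length_cm = 60), "femur_length_cm")
  expect_error(phantom_spec(voxel_mm = 0), "voxel_mm")
  expect_error(generate_phantom(
    phantom_spec(coronal_radius_mm = 100)), "coronal")
})

test_that("a posteriorly bowed phantom is flagged by the reversed screen", {
  vol <- generate_phantom(phantom_spec(voxel_mm = 2, seed = 12,
                                       bow_direction = "posterior"))
  frame <- orient_femur(vol)
  ser <- extract_series(vol, frame)
  expect_true(reversed_curvature_screen(ser)$reversed)
  vol2 <- quick_phantom(seed = 12)
  ser2 <- extract_series(vol2, orient_femur(vol2))
  expect_false(reversed_curvature_screen(ser2)$reversed)
})

test_that("a near-straight phantom yields a near-degenerate total fit", {
  vol <- generate_phantom(phantom_spec(sagittal_radius_mm = 1e6,
                                       voxel_mm = 2, seed = 13))
  ser <- extract_series(vol, orient_femur(vol))
  fit <- segment_radius(ser, "total")
  expect_true(fit$degenerate || fit$R > 2e4)
})

test_that("identity misalignment returns a voxel-identical volume", {
  vol <- quick_phantom(seed = 14)
  same <- apply_rigid_misalignment(vol, c(0, 0, 0))
  expect_identical(same$voxels, vol$voxels)
  expect_error(apply_rigid_misalignment(vol, c(40, 0, 0)), "30")
})

test_that("stem artifact erodes the lumen into a flagged crescent", {
  sp <- phantom_spec(voxel_mm = 1, seed = 15)
  pair <- generate_pair(sp, post_proximal_delta_mm = 0,
                        artifact_levels = c(30, 35))
  frame <- orient_femur(pair$post)
  ser <- extract_series(pair$post, frame)
  qual <- ser$centroids$quality[ser$centroids$height_cm %in% c(30, 35)]
  expect_true(all(qual == "artifact_cleaned"))
  untouched <- ser$centroids$quality[ser$centroids$height_cm %in% c(5, 10, 15)]
  expect_true(all(untouched == "clean"))
})

test_that("null pairs and generated deltas behave at coarse scale", {
  sp <- phantom_spec(voxel_mm = 2, seed = 16)
  pair <- generate_pair(sp, post_proximal_delta_mm = 0)
  expect_equal(pair$truth$post_radii, pair$truth$pre_radii)
  pair2 <- generate_pair(sp, post_proximal_delta_mm = -100)
  expect_equal(pair2$truth$post_radii[3] - pair2$truth$pre_radii[3], -100)
  # the post centreline proximal arc radius is exactly the requested one
  gt <- attr(pair2$post, "ground_truth")
  expect_equal(unname(gt$region_radii["proximal"]),
               sp$region_radii_mm[3] - 100)
  expect_error(generate_pair(sp, post_proximal_delta_mm = -900), "realizable")
})

test_that("cohort generation is seed-deterministic and honours effects", {
  spc <- phantom_spec(seed = 17)
  coh <- cohort_spec(n_patients = 4, proximal_effect_mm = -60, seed = 5)
  a <- generate_cohort(spc, coh)
  b <- generate_cohort(spc, coh)
  expect_identical(lapply(a$series, as.data.frame),
                   lapply(b$series, as.data.frame))
  gt <- a$ground_truth
  tr_pre <- gt[gt$side == "treated" & gt$timepoint == "pre", ]
  tr_post <- gt[gt$side == "treated" & gt$timepoint == "post", ]
  expect_equal(tr_post$R_proximal - tr_pre$R_proximal, rep(-60, 4))
  co <- gt[gt$side == "control", ]
  expect_equal(diff(range(co$R_proximal - co$R_middle)), 0)
})

test_that("zero-noise zero-effect cohorts give p = 1 on every segment", {
  spc <- phantom_spec(seed = 18)
  coh <- cohort_spec(n_patients = 6, proximal_effect_mm = 0,
                     middle_effect_mm = 0, control_effect_mm = 0,
                     observer_noise_mm = 0, scan_noise_mm = 0, seed = 6)
  res <- suppressWarnings(analyze_cohort(generate_cohort(spc, coh)))
  expect_setequal(res$reliable_segments,
                  c("distal", "middle", "proximal", "total"))
  for (seg in res$reliable_segments)
    expect_equal(res$delta[[seg]]$p, 1)
})

test_that("zero observer noise makes the two observers identical", {
  spc <- phantom_spec(seed = 19)
  coh <- cohort_spec(n_patients = 5, observer_noise_mm = 0, seed = 7)
  coh_data <- generate_cohort(spc, coh)
  res <- suppressWarnings(analyze_cohort(coh_data))
  expect_true(all(res$interobserver$reliable))
  o1 <- coh_data$series[["P01.treated.pre.obs1"]]
  o2 <- coh_data$series[["P01.treated.pre.obs2"]]
  expect_equal(o1$centroids$y_ap_mm, o2$centroids$y_ap_mm, tolerance = 1e-12)
})

test_that("volume-output cohorts run the full voxel pipeline", {
  spc <- phantom_spec(voxel_mm = 2, seed = 20)
  coh <- cohort_spec(n_patients = 1, observer_noise_mm = 1, seed = 8)
  cd <- generate_cohort(spc, coh, output = "volumes")
  expect_length(cd$volumes, 4)
  expect_length(cd$series, 8)
  expect_s3_class(cd$series[[1]], "centroid_series")
  expect_true(all(vapply(cd$series, function(s) s$complete, logical(1))))
})
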