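test_that("a standard-pose phantom fits an identity orientation", {
  vol <- generate_phantom(phantom_spec(voxel_mm = 2, seed = 1),
                          standard_pose = TRUE)
  tf <- fit_posterior_tangency(vol)
  expect_lt(rotation_angle_deg(tf$rotation), 1e-6)
  frame <- set_reference_plane(vol, tf)
  # condyle spheres rest on z = 0 by construction
  expect_lt(abs(frame$z_zero - 0), 1.1)
})

test_that("a known rigid misalignment is recovered by the tangency fit", {
  vol <- generate_phantom(phantom_spec(voxel_mm = 2, seed = 2),
                          standard_pose = TRUE)
  ang <- c(14, -9, 6)
  vol2 <- apply_rigid_misalignment(vol, ang, c(10, 5, -4))
  tf <- fit_posterior_tangency(vol2)
  truth <- attr(vol2, "true_transform")
  resid <- tf$rotation %*% truth$rotation    # should be ~identity
  expect_lt(rotation_angle_deg(resid), 0.5)
})

test_that("missing landmarks raise errors naming the region", {
  vol <- quick_phantom()
  vol$voxels[vol$voxels == vol$label_map[["posterior_condyle_left"]]] <- 0L
  expect_error(fit_posterior_tangency(vol), "posterior_condyle_left")
  vol2 <- quick_phantom()
  vol2$voxels[vol2$voxels == vol2$label_map[["lesser_trochanter"]]] <- 0L
  frame <- orient_femur(vol2)
  expect_error(eligibility_length(vol2, frame), "lesser_trochanter")
})

test_that("degenerate support points are rejected", {
  # three landmark blobs along one line
  arr <- array(0L, c(40, 20, 60))
  arr[18:22, 2:4, 2:6] <- 2L
  arr[18:22, 2:4, 10:14] <- 3L
  arr[18:22, 2:4, 50:54] <- 4L
  arr[15:25, 8:12, 5:55] <- 1L
  vol <- labeled_volume(arr, c(1, 1, 1), c(0, 0, 0),
                        PHANTOM_LABELS[c("canal", "posterior_condyle_left",
                                         "posterior_condyle_right",
                                         "greater_trochanter")])
  expect_error(fit_posterior_tangency(vol), "degenerate")
})

test_that("the lower of two condyles defines the reference plane", {
  lay <- default_landmarks()
  vol <- generate_phantom(phantom_spec(voxel_mm = 1, seed = 3,
                                       landmark_layout = lay),
                          standard_pose = TRUE)
  # push the left condyle up by 6 mm: the right one must now set z = 0
  lab <- vol$label_map
  idx <- which(vol$voxels == lab[["posterior_condyle_left"]], arr.ind = TRUE)
  vol$voxels[idx] <- 0L
  idx[, 3] <- idx[, 3] + 6L
  vol$voxels[idx] <- lab[["posterior_condyle_left"]]
  frame <- orient_femur(vol)
  right <- femcurve:::oriented_coords(vol, frame, "posterior_condyle_right")
  left <- femcurve:::oriented_coords(vol, frame, "posterior_condyle_left")
  expect_lt(abs(min(right[, 3])), 1e-9)
  expect_gt(min(left[, 3]), 4)
})

test_that("translating the volume changes no radius", {
  vol <- quick_phantom(seed = 4)
  r0 <- measure_segments(vol)
  vol2 <- vol
  vol2$origin <- vol$origin + c(0, 0, 30)
  r1 <- measure_segments(vol2)
  expect_equal(r1, r0, tolerance = 1e-9)
})

test_that("level heights are measured from the reference plane", {
  vol <- generate_phantom(phantom_spec(voxel_mm = 1, seed = 5),
                          standard_pose = TRUE)
  frame <- orient_femur(vol)
  mask <- extract_level(vol, frame, 5)
  expect_lt(abs(mean(mask$coords[, 3]) - 50), 1.1)
  # shifting the reference plane shifts the sampled slab accordingly
  frame$z_zero <- frame$z_zero + 12
  mask2 <- extract_level(vol, frame, 5)
  expect_lt(abs(mean(mask2$coords[, 3]) - 50), 1.1)
})

test_that("eligibility window is inclusive at 35 and 40 cm", {
  # the comparison rule itself: strictly <35 or >40 excludes
  expect_false(femcurve:::eligible_window(34.9))
  expect_true(femcurve:::eligible_window(35))
  expect_true(femcurve:::eligible_window(40))
  expect_false(femcurve:::eligible_window(40.1))
  # through the voxel pipeline, with margins above the voxel size
  for (len in c(34, 37, 41)) {
    vol <- generate_phantom(phantom_spec(femur_length_cm = len, voxel_mm = 2,
                                         seed = 6))
    frame <- orient_femur(vol)
    el <- eligibility_length(vol, frame)
    expect_lt(abs(el$length_cm - len), 0.25)
    expect_identical(el$eligible, len >= 35 && len <= 40,
                     info = paste("length", len))
  }
})

test_that("orientation is idempotent on centroids", {
  vol <- quick_phantom(seed = 8)
  frame <- orient_femur(vol)
  ser1 <- extract_series(vol, frame)
  # second pass: fit on top of the first (compose transforms)
  tf2 <- fit_posterior_tangency(vol)
  frame2 <- set_reference_plane(vol, tf2)
  ser2 <- extract_series(vol, frame2)
  d <- max(abs(ser1$centroids$y_ap_mm - ser2$centroids$y_ap_mm), na.rm = TRUE)
  expect_lt(d, sqrt(3) * 2)
})
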