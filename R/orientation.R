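#' Fit the posterior tangency plane and standard orientation
#'
#' Finds the rigid rotation that brings the femur into the standard
#' configuration: a plane simultaneously tangent to the most posterior
#' portion of both femoral condyles and the posterior margin of the greater
#' trochanter becomes the plane `y = const`, with the bone anterior (larger
#' y) of it. The residual degree of freedom (rotation about the plane
#' normal) is fixed by aligning the inter-condylar support direction with
#' the medio-lateral axis, which is the condylar-overlap condition of the
#' standard lateral view.
#'
#' The fit iterates: under the current candidate rotation, the posterior
#' support point of each landmark region is the centroid of its voxels lying
#' within half a voxel of the region's posterior extreme; the orthonormal
#' frame built from the three support points defines the next rotation.
#' Iteration stops when the incremental rotation falls below 0.01 degrees
#' (at most 50 iterations).
#'
#' @param volume A [labeled_volume()] with nonempty condyle and
#'   greater-trochanter labels.
#' @return A [rigid_transform()] (pure rotation; zero translation) mapping
#'   input physical coordinates to standard-orientation coordinates.
#' @export
fit_posterior_tangency <- function(volume) {
  validate_labels(volume, c("posterior_condyle_left", "posterior_condyle_right",
                            "greater_trochanter", "canal"))
  pc1 <- label_coords(volume, "posterior_condyle_left")
  pc2 <- label_coords(volume, "posterior_condyle_right")
  gt  <- label_coords(volume, "greater_trochanter")
  canal_mid <- colMeans(label_coords(volume, "canal"))
  half_vox <- 0.5 * min(volume$spacing)

  rot <- diag(3)
  for (it in seq_len(50L)) {
    s1 <- posterior_support(pc1 %*% t(rot), half_vox)
    s2 <- posterior_support(pc2 %*% t(rot), half_vox)
    s3 <- posterior_support(gt  %*% t(rot), half_vox)
    check_support_noncollinear(s1, s2, s3)
    frame <- support_frame(s1, s2, s3, drop(rot %*% canal_mid))
    step <- t(frame)                      # maps current coords to new frame
    rot <- step %*% rot
    if (rotation_angle_deg(step) < 0.01) break
  }
  rigid_transform(rot, c(0, 0, 0))
}

# centroid of the voxels within `tol` of the region's posterior (min-y) extreme
posterior_support <- function(pts, tol) {
  y <- pts[, 2]
  colMeans(pts[y <= min(y) + tol, , drop = FALSE])
}

check_support_noncollinear <- function(s1, s2, s3) {
  v1 <- s2 - s1; v2 <- s3 - s1
  n <- crossprod3(v1, v2)
  # distance of s3 from the line s1-s2 (and permutations) under 1 mm => degenerate
  d <- sqrt(sum(n^2)) / max(sqrt(sum(v1^2)), 1e-12)
  if (d < 1) stop("degenerate posterior support points: the three tangency ",
                  "points are within 1 mm of a common line")
  invisible(NULL)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# orthonormal frame (columns x_ML, y_AP, z_SI) from the three posterior
# support points; `anterior_ref` disambiguates the anterior direction
support_frame <- function(s1, s2, s3, anterior_ref) {
  n <- crossprod3(s2 - s1, s3 - s1)
  n <- n / sqrt(sum(n^2))
  cmid <- (s1 + s2) / 2
  if (sum(n * (anterior_ref - cmid)) < 0) n <- -n   # bone lies anterior
  ez <- s3 - cmid
  ez <- ez - sum(ez * n) * n                        # superior, in-plane
  ez <- ez / sqrt(sum(ez^2))
  ex <- crossprod3(n, ez)
  cbind(ex, n, ez)
}

#' Define the reference axial plane and world frame
#'
#' The reference axial plane sits at the lowest margin of the two condyles
#' (the smaller of the two regions' minimum z after orientation); all level
#' heights are measured from it. Axis roles after orientation are fixed:
#' x medio-lateral, y antero-posterior (anterior positive), z
#' inferior-superior (superior positive, z = 0 at the reference plane).
#'
#' @param volume A [labeled_volume()].
#' @param transform The orientation transform from [fit_posterior_tangency()].
#' @return An object of class `world_frame` with elements `transform`,
#'   `z_zero` (reference-plane height in oriented coordinates, mm),
#'   `axis_roles`, `ap_positive`, `si_positive`.
#' @export
set_reference_plane <- function(volume, transform) {
  validate_labels(volume, c("posterior_condyle_left", "posterior_condyle_right"))
  zc <- c(apply_rigid(transform, label_coords(volume, "posterior_condyle_left"))[, 3],
          apply_rigid(transform, label_coords(volume, "posterior_condyle_right"))[, 3])
  structure(list(transform = transform, z_zero = min(zc),
                 axis_roles = c(x = "ML", y = "AP", z = "SI"),
                 ap_positive = "anterior", si_positive = "superior"),
            class = "world_frame")
}

#' @export
print.world_frame <- function(x, ...) {
  cat("World frame: x=ML, y=AP (anterior+), z=SI (superior+); reference plane",
      "at oriented z =", format(x$z_zero, digits = 6), "mm\n")
  invisible(x)
}

# oriented coordinates of a label region, z measured from the reference plane
oriented_coords <- function(volume, frame, role) {
  pts <- apply_rigid(frame$transform, label_coords(volume, role))
  pts[, 3] <- pts[, 3] - frame$z_zero
  pts
}

#' Femoral segment length and eligibility
#'
#' Length from the inferior border of the lesser trochanter to the
#' transepicondylar axis (the segment joining the two epicondyle-region
#' centroids), in cm. Femurs shorter than 35 cm or longer than 40 cm are
#' ineligible; the window boundaries are inclusive since the exclusion rule
#' is strictly "<35 cm or >40 cm".
#'
#' @param volume A [labeled_volume()] with lesser-trochanter and both
#'   epicondyle labels.
#' @param frame A `world_frame` from [set_reference_plane()].
#' @return A list with `length_cm` and logical `eligible`.
#' @export
eligibility_length <- function(volume, frame) {
  validate_labels(volume, c("lesser_trochanter", "epicondyle_medial",
                            "epicondyle_lateral"))
  lt <- oriented_coords(volume, frame, "lesser_trochanter")
  em <- colMeans(oriented_coords(volume, frame, "epicondyle_medial"))
  el <- colMeans(oriented_coords(volume, frame, "epicondyle_lateral"))
  tea_z <- (em[3] + el[3]) / 2
  length_cm <- (min(lt[, 3]) - tea_z) / 10
  list(length_cm = unname(length_cm),
       eligible = eligible_window(length_cm))
}

# the exclusion rule is strictly "<35 or >40", so the boundaries pass
eligible_window <- function(length_cm) {
  length_cm >= 35 && length_cm <= 40
}

#' One-call standard orientation
#'
#' Convenience wrapper: fits the posterior tangency transform and the
#' reference plane in one step.
#'
#' @param volume A [labeled_volume()].
#' @return A `world_frame`.
#' @export
orient_femur <- function(volume) {
  set_reference_plane(volume, fit_posterior_tangency(volume))
}
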