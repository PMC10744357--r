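#' Rigid transform (rotation + translation)
#'
#' A proper rigid transform: an orthonormal rotation matrix with determinant
#' +1 and a translation vector in mm. Points are mapped as `R p + t`.
#'
#' @param rotation 3x3 orthonormal matrix, det +1.
#' @param translation numeric length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal (tolerance 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must have determinant +1 (no reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf A `rigid_transform`.
#' @param pts n x 3 matrix (or length-3 vector) of points in mm.
#' @return Transformed points, same shape as input.
#' @export
apply_rigid <- function(tf, pts) {
  single <- is.null(dim(pts))
  pts <- matrix(pts, ncol = 3L)
  out <- pts %*% t(tf$rotation)
  out <- sweep(out, 2L, tf$translation, "+")
  if (single) drop(out) else out
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(tf) {
  rigid_transform(t(tf$rotation), -drop(t(tf$rotation) %*% tf$translation))
}

#' Compose rigid transforms (`a` applied after `b`)
#' @param a,b `rigid_transform` objects.
#' @return The composite transform `a %then% b`: first `b`, then `a`.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Rotation matrix from extrinsic x-y-z Euler angles
#'
#' Rotations about the ML (x), AP (y) and SI (z) axes, composed as
#' `Rz %*% Ry %*% Rx`.
#'
#' @param angles_deg numeric length-3, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_xyz <- function(angles_deg) {
  a <- angles_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
  ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
  rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Angle of a rotation matrix
#' @param rot 3x3 rotation matrix.
#' @return Rotation angle in degrees.
#' @export
rotation_angle_deg <- function(rot) {
  c_ <- (sum(diag(rot)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Export a rigid transform as a 4x4 homogeneous matrix (JSON-friendly)
#' @param tf A `rigid_transform`.
#' @param path Optional file path; when given, the matrix is written as JSON.
#' @return The 4x4 matrix, invisibly when written to file.
#' @export
as_homogeneous <- function(tf, path = NULL) {
  m <- rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
  if (!is.null(path)) {
    jsonlite::write_json(m, path, digits = NA, matrix = "rowmajor")
    return(invisible(m))
  }
  m
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (angle", format(rotation_angle_deg(x$rotation), digits = 4),
      "deg, translation", paste(format(x$translation, digits = 4), collapse = ", "),
      "mm)\n")
  invisible(x)
}
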