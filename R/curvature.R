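#' Circumcircle through three sagittal points
#'
#' Exactly one circle passes through three non-aligned points. The
#' circumcentre is computed in closed form (the intersection of the two
#' perpendicular bisectors, written with the standard circumcircle
#' determinant algebra, which is equivalent to the slope-form centre
#' equations but free of their vertical-chord singularities) and the radius
#' of curvature R is the distance from the centre to the first point.
#'
#' Points are sagittal-plane pairs `(y, z)`: y antero-posterior (anterior
#' positive), z inferior-superior. The bowing direction is `"anterior"`
#' when the middle point lies anterior to the chord joining the outer
#' points (procurvatum), `"posterior"` otherwise (recurvatum).
#'
#' Collinearity is judged on the normalised triangle (coordinates divided by
#' the longest chord) so the tolerance is scale-free: normalised area below
#' 1e-9 flags a degenerate fit with infinite radius instead of a crash.
#' Coincident points are an error.
#'
#' @param p1,p2,p3 Numeric length-2 vectors `(y, z)` in mm, ordered
#'   inferior to superior.
#' @return An object of class `circle_fit` with elements `yC`, `zC`
#'   (circumcentre, mm), `R` (radius, mm; `Inf` when degenerate),
#'   `direction` (`"anterior"`, `"posterior"` or `NA`), `degenerate`.
#' @export
circumcircle <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  stopifnot(length(p1) == 2L, length(p2) == 2L, length(p3) == 2L)
  d12 <- sqrt(sum((p2 - p1)^2)); d13 <- sqrt(sum((p3 - p1)^2))
  d23 <- sqrt(sum((p3 - p2)^2))
  scale <- max(d12, d13, d23)
  if (min(d12, d13, d23) <= 1e-12 * max(scale, 1))
    stop("coincident points: the circumcircle is undefined")
  a <- p2 - p1
  b <- p3 - p1
  cross <- a[1] * b[2] - a[2] * b[1]
  norm_area <- abs(cross) / (2 * scale^2)
  if (norm_area < 1e-9) {
    return(structure(list(yC = NA_real_, zC = NA_real_, R = Inf,
                          direction = NA_character_, degenerate = TRUE),
                     class = "circle_fit"))
  }
  a2 <- sum(a^2); b2 <- sum(b^2)
  uy <- (b[2] * a2 - a[2] * b2) / (2 * cross)
  uz <- (a[1] * b2 - b[1] * a2) / (2 * cross)
  centre <- p1 + c(uy, uz)
  r <- sqrt(uy^2 + uz^2)
  # side of the chord p1-p3 on which the middle point bulges
  chord <- p3 - p1
  s <- chord[2] * (p2[1] - p1[1]) - chord[1] * (p2[2] - p1[2])
  # s > 0 iff p2 lies on the +y (anterior) side of the chord as z increases
  direction <- if (sign(chord[2]) * s > 0) "anterior" else "posterior"
  structure(list(yC = unname(centre[1]), zC = unname(centre[2]), R = r,
                 direction = direction, degenerate = FALSE),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) cat("Circle fit: degenerate (collinear), R = Inf\n")
  else cat("Circle fit: R =", format(x$R, digits = 6), "mm,",
           x$direction, "bow, centre (y,z) = (",
           format(x$yC, digits = 6), ",", format(x$zC, digits = 6), ")\n")
  invisible(x)
}

not_computable <- function(reason) {
  structure(list(yC = NA_real_, zC = NA_real_, R = NA_real_,
                 direction = NA_character_, degenerate = NA,
                 computable = FALSE, reason = reason),
            class = c("not_computable", "circle_fit"))
}

#' @export
print.not_computable <- function(x, ...) {
  cat("Segment fit not computable:", x$reason, "\n")
  invisible(x)
}

is_computable <- function(fit) {
  !inherits(fit, "not_computable") && !isTRUE(fit$degenerate)
}

#' Per-segment radius of curvature from a centroid series
#'
#' The canonical centroid triplets are: distal 5/10/15 cm, middle
#' 15/20/25 cm, proximal 25/30/35 cm, and total (whole femur) 5/20/35 cm.
#' Centroids are projected to the sagittal plane, i.e. the fit uses the
#' `(y_ap, z_si)` pairs. A segment whose triplet touches a missing level is
#' not-computable; the other segments are unaffected.
#'
#' @param series A [centroid_series()].
#' @param segment One of `"distal"`, `"middle"`, `"proximal"`, `"total"`.
#' @return A `circle_fit`, or a `not_computable` object when a triplet
#'   centroid is missing.
#' @export
segment_radius <- function(series, segment) {
  segment <- match.arg(segment, names(SEGMENT_TRIPLETS))
  heights <- SEGMENT_TRIPLETS[[segment]]
  cen <- series$centroids
  rows <- cen[match(heights, cen$height_cm), , drop = FALSE]
  if (any(is.na(rows$y_ap_mm)) || any(rows$quality == "missing"))
    return(not_computable(paste0("missing centroid at ",
      paste(heights[is.na(rows$y_ap_mm) | rows$quality == "missing"],
            collapse = ", "), " cm")))
  fit <- circumcircle(c(rows$y_ap_mm[1], rows$z_si_mm[1]),
                      c(rows$y_ap_mm[2], rows$z_si_mm[2]),
                      c(rows$y_ap_mm[3], rows$z_si_mm[3]))
  fit$segment <- segment
  fit$heights_cm <- heights
  fit
}

#' All four segment radii for one femur/timepoint
#'
#' @param series A [centroid_series()].
#' @return An object of class `segment_radii` carrying the series metadata
#'   and one `circle_fit` (or not-computable marker) per segment.
#' @export
segment_radii <- function(series) {
  fits <- lapply(names(SEGMENT_TRIPLETS), function(s) segment_radius(series, s))
  names(fits) <- names(SEGMENT_TRIPLETS)
  structure(c(list(patient_id = series$patient_id, side = series$side,
                   timepoint = series$timepoint, observer = series$observer),
              fits),
            class = "segment_radii")
}

#' @export
print.segment_radii <- function(x, ...) {
  cat("Segment radii:", x$patient_id, x$side, x$timepoint,
      paste0("(observer ", x$observer, ")\n"))
  for (s in names(SEGMENT_TRIPLETS)) {
    cat(sprintf("  %-8s ", s))
    print(x[[s]])
  }
  invisible(x)
}

#' Pre/post change in radius of curvature
#'
#' The follow-up minus baseline radius for one femur segment:
#' `delta = R_post - R_pre` in mm, sign preserved (negative means a tighter
#' bow, i.e. increased bowing, at follow-up). Undefined (NA, with a reason)
#' when either timepoint's fit is degenerate or not-computable.
#'
#' @param pre,post `segment_radii` for the same patient and side at the
#'   baseline and follow-up timepoints.
#' @param segment Segment name.
#' @return A list with `patient_id`, `side`, `segment`, `delta_mm` (NA when
#'   undefined) and `reason` (NULL when defined).
#' @export
delta_radius <- function(pre, post, segment) {
  segment <- match.arg(segment, names(SEGMENT_TRIPLETS))
  if (!identical(pre$patient_id, post$patient_id) ||
      !identical(pre$side, post$side))
    stop("pre and post radii must come from the same patient and side")
  f1 <- pre[[segment]]; f2 <- post[[segment]]
  if (!is_computable(f1) || !is_computable(f2)) {
    reason <- paste0(if (!is_computable(f1)) "pre " else "post ",
                     "fit ", if (inherits(if (!is_computable(f1)) f1 else f2,
                                          "not_computable"))
                       "not computable" else "degenerate")
    return(list(patient_id = pre$patient_id, side = pre$side,
                segment = segment, delta_mm = NA_real_, reason = reason))
  }
  list(patient_id = pre$patient_id, side = pre$side, segment = segment,
       delta_mm = f2$R - f1$R, reason = NULL)
}

#' Screen for reversed (posterior) whole-femur curvature
#'
#' Femurs whose whole-femur bow points posteriorly (recurvatum, a reversed
#' radius of curvature due to marked dysmorphism) are excluded from cohort
#' analysis. A degenerate (straight) total fit gives an indeterminate
#' result, also excluded, with the reason recorded.
#'
#' @param series A [centroid_series()].
#' @return A list with `reversed` (TRUE/FALSE/NA) and `reason`.
#' @export
reversed_curvature_screen <- function(series) {
  fit <- segment_radius(series, "total")
  if (inherits(fit, "not_computable"))
    return(list(reversed = NA, reason = fit$reason))
  if (isTRUE(fit$degenerate))
    return(list(reversed = NA,
                reason = "degenerate total fit (straight femur)"))
  list(reversed = fit$direction == "posterior", reason = NULL)
}
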