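#' Default canal diameter profile
#'
#' Endosteal canal diameter versus height above the reference plane:
#' a wide distal metaphysis narrowing to an isthmus near 17-18 cm and
#' flaring again proximally, in the range reported for adult femoral
#' canals. Linear interpolation between the knots, constant beyond them.
#'
#' @return Data frame with columns `height_mm`, `diameter_mm`.
#' @export
default_canal_profile <- function() {
  data.frame(height_mm = c(30, 100, 175, 250, 320, 385),
             diameter_mm = c(26, 16, 11, 13, 18, 24))
}

#' Default landmark layout for synthetic femurs
#'
#' Positions and radii (mm) of the spherical landmark label regions, in
#' standard-pose coordinates (y = 0 is the posterior tangency plane, z = 0
#' the lowest condyle margin). The posterior surfaces of both condyles and
#' of the greater trochanter touch y = 0, so the generating pose is the
#' standard configuration by construction.
#'
#' @return Named list of layout parameters.
#' @export
default_landmarks <- function() {
  list(condyle_r = 14, condyle_dx = 22,
       troch_r = 12, troch_z = 402,
       epicond_r = 6, epicond_dx = 32, epicond_z = 25, epicond_y = 20,
       lt_r = 6, lt_x = 20, lt_y = 35,
       canal_z = c(30, 385), z_apex = 200, junctions = c(150, 250),
       apex_y = 45)
}

#' Specification of a synthetic femur-canal phantom
#'
#' The canal is a tube swept along a piecewise circular arc in the sagittal
#' (y, z) plane (optionally composed with a coronal arc), with the diameter
#' profile of `canal_profile`. Landmark label blobs are placed so that the
#' posterior tangency fit and the eligibility length recover the generating
#' pose and length. The seed drives the acquisition pose: scanner grids are
#' tilted by up to `acquisition_tilt_deg` about the ML and AP axes with a
#' random sub-voxel grid offset, emulating the arbitrary patient positioning
#' of clinical CT (and decorrelating voxelisation error across slices).
#'
#' @param sagittal_radius_mm Ground-truth arc radius of the canal centreline
#'   in the sagittal plane (mm).
#' @param coronal_radius_mm Optional secondary coronal bow radius (mm);
#'   `NULL` for a straight coronal projection.
#' @param canal_profile Diameter profile, see [default_canal_profile()].
#' @param femur_length_cm Lesser trochanter to transepicondylar axis, cm
#'   (must lie in \[25, 50\]).
#' @param voxel_mm Isotropic voxel size (mm).
#' @param bow_direction `"anterior"` (procurvatum, normal) or `"posterior"`.
#' @param acquisition_tilt_deg Half-range of the seeded scanner tilt
#'   (degrees) about the ML and AP axes.
#' @param landmark_layout See [default_landmarks()].
#' @param region_radii_mm Optional length-3 vector (distal, middle,
#'   proximal) overriding `sagittal_radius_mm` per region; the three arcs
#'   are blended C1-continuously at the junction heights (15 and 25 cm).
#' @param seed Integer seed; identical specs and seeds give bit-identical
#'   volumes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(sagittal_radius_mm = 1000, coronal_radius_mm = NULL,
                         canal_profile = default_canal_profile(),
                         femur_length_cm = 37, voxel_mm = 1,
                         bow_direction = c("anterior", "posterior"),
                         acquisition_tilt_deg = 12,
                         landmark_layout = default_landmarks(),
                         region_radii_mm = NULL, seed = 1L) {
  bow_direction <- match.arg(bow_direction)
  if (voxel_mm <= 0) stop("voxel_mm must be positive")
  if (femur_length_cm < 25 || femur_length_cm > 50)
    stop("femur_length_cm must lie within [25, 50]")
  zr <- landmark_layout$canal_z
  chord <- zr[2] - zr[1]
  radii <- if (is.null(region_radii_mm)) rep(sagittal_radius_mm, 3)
           else as.numeric(region_radii_mm)
  if (any(radii <= chord / 2))
    stop("sagittal radius must exceed half the canal chord (",
         chord / 2, " mm); the arc is not geometrically realizable")
  structure(list(sagittal_radius_mm = sagittal_radius_mm,
                 coronal_radius_mm = coronal_radius_mm,
                 canal_profile = canal_profile,
                 femur_length_cm = femur_length_cm, voxel_mm = voxel_mm,
                 bow_direction = bow_direction,
                 acquisition_tilt_deg = acquisition_tilt_deg,
                 landmark_layout = landmark_layout,
                 region_radii_mm = radii, seed = as.integer(seed)),
            class = "phantom_spec")
}

# evaluate code with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# piecewise C1 sagittal centreline: three arcs with radii (distal, middle,
# proximal), sharing tangents at the junction heights; returns vectorised
# y(z) plus the arc centres for oracle use
make_centerline <- function(region_radii, direction, layout) {
  s <- if (direction == "anterior") 1 else -1
  za <- layout$z_apex; jn <- layout$junctions; zr <- layout$canal_z
  rm_ <- region_radii[2]
  cm <- c(layout$apex_y - s * rm_, za)
  arc_y <- function(centre, radius, z)
    centre[1] + s * sqrt(pmax(radius^2 - (z - centre[2])^2, 0))
  attach_arc <- function(z_j, radius) {
    p <- c(arc_y(cm, rm_, z_j), z_j)
    u <- (cm - p) / rm_
    p + radius * u
  }
  cd <- attach_arc(jn[1], region_radii[1])
  cp <- attach_arc(jn[2], region_radii[3])
  check <- function(centre, radius, zlo, zhi) {
    if (max(abs(c(zlo, zhi) - centre[2])) >= radius)
      stop("unrealizable centreline: arc of radius ", radius,
           " mm cannot span heights ", zlo, "-", zhi, " mm")
  }
  check(cd, region_radii[1], zr[1], jn[1])
  check(cm, rm_, jn[1], jn[2])
  check(cp, region_radii[3], jn[2], zr[2])
  fy <- function(z) {
    y <- numeric(length(z))
    lo <- z < jn[1]; hi <- z > jn[2]; mid <- !lo & !hi
    y[lo] <- arc_y(cd, region_radii[1], z[lo])
    y[mid] <- arc_y(cm, rm_, z[mid])
    y[hi] <- arc_y(cp, region_radii[3], z[hi])
    y
  }
  list(fy = fy, centres = list(distal = cd, middle = cm, proximal = cp),
       region_radii = region_radii, direction = direction)
}

make_coronal <- function(coronal_radius, layout) {
  if (is.null(coronal_radius)) return(function(z) numeric(length(z)))
  za <- layout$z_apex; zr <- layout$canal_z
  if (max(abs(zr - za)) >= coronal_radius)
    stop("unrealizable coronal arc")
  cc <- c(-coronal_radius, za)
  function(z) cc[1] + sqrt(pmax(coronal_radius^2 - (z - cc[2])^2, 0))
}

phantom_spheres <- function(spec) {
  lay <- spec$landmark_layout
  lt_z <- lay$epicond_z + spec$femur_length_cm * 10 + lay$lt_r
  list(
    posterior_condyle_left = list(c(-lay$condyle_dx, lay$condyle_r, lay$condyle_r),
                                  lay$condyle_r),
    posterior_condyle_right = list(c(lay$condyle_dx, lay$condyle_r, lay$condyle_r),
                                   lay$condyle_r),
    greater_trochanter = list(c(0, lay$troch_r, lay$troch_z), lay$troch_r),
    lesser_trochanter = list(c(lay$lt_x, lay$lt_y, lt_z), lay$lt_r),
    epicondyle_medial = list(c(-lay$epicond_dx, lay$epicond_y, lay$epicond_z),
                             lay$epicond_r),
    epicondyle_lateral = list(c(lay$epicond_dx, lay$epicond_y, lay$epicond_z),
                              lay$epicond_r))
}

#' Generate a labelled femur-canal phantom volume
#'
#' Rasterises the tube and landmark spheres of a [phantom_spec()] onto a
#' scanner voxel grid. The acquisition pose (tilt about the ML and AP axes
#' plus sub-voxel grid offset) is drawn from the spec's seed;
#' `standard_pose = TRUE` forces the exact axis-aligned standard pose with
#' a half-voxel-centred grid, for fixed-point tests.
#'
#' The returned volume carries a `ground_truth` attribute with the
#' generating region radii, bow direction, acquisition rotation
#' (anatomical to scanner), and analytic centreline.
#'
#' @param spec A [phantom_spec()].
#' @param standard_pose Logical.
#' @return A [labeled_volume()].
#' @export
generate_phantom <- function(spec, standard_pose = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_mm
  lay <- spec$landmark_layout
  cl <- make_centerline(spec$region_radii_mm, spec$bow_direction, lay)
  fx <- make_coronal(spec$coronal_radius_mm, lay)
  radf <- approxfun(spec$canal_profile$height_mm,
                    spec$canal_profile$diameter_mm / 2, rule = 2)
  pose <- with_seed(spec$seed, {
    if (standard_pose) list(rot = diag(3), off = rep(0.5 * h, 3))
    else {
      t_ <- spec$acquisition_tilt_deg
      ang <- runif(2, -t_, t_)
      list(rot = rotation_xyz(c(ang[1], ang[2], 0)), off = runif(3, 0, h))
    }
  })
  m <- pose$rot                               # anatomical -> scanner
  spheres <- phantom_spheres(spec)

  # anatomical bounding box of all primitives
  zg <- seq(lay$canal_z[1], lay$canal_z[2], by = 1)
  rmax <- max(radf(zg))
  ax_lo <- c(min(fx(zg)) - rmax, min(cl$fy(zg)) - rmax, lay$canal_z[1])
  ax_hi <- c(max(fx(zg)) + rmax, max(cl$fy(zg)) + rmax, lay$canal_z[2])
  for (sp in spheres) {
    ax_lo <- pmin(ax_lo, sp[[1]] - sp[[2]])
    ax_hi <- pmax(ax_hi, sp[[1]] + sp[[2]])
  }
  corners <- as.matrix(expand.grid(x = c(ax_lo[1], ax_hi[1]),
                                   y = c(ax_lo[2], ax_hi[2]),
                                   z = c(ax_lo[3], ax_hi[3])))
  sc <- corners %*% t(m)
  lo <- apply(sc, 2, min) - 2 * h
  hi <- apply(sc, 2, max) + 2 * h
  origin <- lo + pose$off
  dims <- pmax(1L, ceiling((hi - origin) / h)) + 1L

  xs <- origin[1] + (seq_len(dims[1]) - 1) * h
  ys <- origin[2] + (seq_len(dims[2]) - 1) * h
  xmat <- matrix(xs, dims[1], dims[2])
  ymat <- matrix(ys, dims[1], dims[2], byrow = TRUE)
  mi <- t(m)                                  # scanner -> anatomical
  sph_sc <- lapply(spheres, function(sp) list(drop(m %*% sp[[1]]), sp[[2]]))
  vox <- array(0L, dim = dims)
  zr <- lay$canal_z
  for (k in seq_len(dims[3])) {
    zsc <- origin[3] + (k - 1) * h
    xa <- mi[1, 1] * xmat + mi[1, 2] * ymat + mi[1, 3] * zsc
    ya <- mi[2, 1] * xmat + mi[2, 2] * ymat + mi[2, 3] * zsc
    za <- mi[3, 1] * xmat + mi[3, 2] * ymat + mi[3, 3] * zsc
    layer <- matrix(0L, dims[1], dims[2])
    inz <- za >= zr[1] & za <= zr[2]
    if (any(inz)) {
      zv <- za[inz]
      dx <- xa[inz] - fx(zv)
      dy <- ya[inz] - cl$fy(zv)
      hit <- dx * dx + dy * dy <= radf(zv)^2
      sel <- which(inz)[hit]
      layer[sel] <- PHANTOM_LABELS[["canal"]]
    }
    for (role in names(sph_sc)) {
      cs <- sph_sc[[role]][[1]]; r <- sph_sc[[role]][[2]]
      dz <- zsc - cs[3]
      if (abs(dz) >= r) next
      rr2 <- r^2 - dz^2
      hit <- (xmat - cs[1])^2 + (ymat - cs[2])^2 <= rr2
      layer[hit] <- PHANTOM_LABELS[[role]]
    }
    vox[, , k] <- layer
  }
  vol <- labeled_volume(vox, rep(h, 3), origin, PHANTOM_LABELS)
  attr(vol, "ground_truth") <- list(
    region_radii = setNames(cl$region_radii, c("distal", "middle", "proximal")),
    direction = spec$bow_direction,
    rotation = m, centerline = cl, coronal = fx, canal_radius = radf,
    spec = spec, standard_pose = standard_pose)
  vol
}

#' Crescent lumen erosion emulating a prosthetic stem
#'
#' At the given level heights, canal voxels falling inside an
#' anteriorly-offset stem disc are removed, leaving a posterior crescent of
#' lumen: the label-mask analogue of the segmentation artifact around a
#' cementless femoral stem. Only label masks are modelled; no metal
#' streaking.
#'
#' @param volume A phantom [labeled_volume()] from [generate_phantom()].
#' @param levels_cm Heights (cm) whose neighbourhood (+/- 6 mm) is affected.
#' @return The eroded volume (ground-truth attribute preserved).
#' @export
apply_stem_artifact <- function(volume, levels_cm) {
  gt <- attr(volume, "ground_truth")
  if (is.null(gt)) stop("volume carries no ground-truth geometry")
  idx <- which(volume$voxels == volume$label_map[["canal"]], arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2L, volume$spacing, "*"), 2L, volume$origin, "+")
  pa <- pts %*% gt$rotation                   # scanner -> anatomical (R^T p)'
  za <- pa[, 3]
  affected <- rep(FALSE, length(za))
  for (hcm in levels_cm)
    affected <- affected | abs(za - hcm * 10) <= 6
  if (!any(affected)) return(volume)
  rad <- gt$canal_radius(za)
  dy <- pa[, 2] - (gt$centerline$fy(za) + 0.35 * rad)
  dx <- pa[, 1] - gt$coronal(za)
  inside_stem <- affected & (dx^2 + dy^2 <= (0.8 * rad)^2)
  kill <- idx[inside_stem, , drop = FALSE]
  volume$voxels[kill] <- 0L
  volume
}

#' Generate a paired pre/post phantom
#'
#' The post phantom re-bends the proximal portion of the centreline so its
#' local arc radius is `sagittal_radius_mm + post_proximal_delta_mm`
#' (blended C1-continuously into the unchanged middle/distal centreline at
#' 25 cm), optionally also re-bending the middle region, and applies
#' crescent lumen erosion at `artifact_levels`. Pre and post are rasterised
#' as independent acquisitions (different seeded poses), as two CT scans of
#' the same patient would be.
#'
#' @param spec A [phantom_spec()] describing the baseline femur.
#' @param post_proximal_delta_mm Change of the proximal arc radius (mm);
#'   negative = tighter bow at follow-up.
#' @param artifact_levels Heights (cm) with stem artifact on the post
#'   volume, e.g. `c(25, 30, 35)`; `NULL` for none.
#' @param post_middle_delta_mm Change of the middle arc radius (mm).
#' @return List with elements `pre`, `post` (labelled volumes) and
#'   `truth` (the generating radii and deltas).
#' @export
generate_pair <- function(spec, post_proximal_delta_mm,
                          artifact_levels = NULL, post_middle_delta_mm = 0) {
  r0 <- spec$region_radii_mm
  post_radii <- c(r0[1], r0[2] + post_middle_delta_mm,
                  r0[3] + post_proximal_delta_mm)
  post_spec <- spec
  post_spec$region_radii_mm <- post_radii
  post_spec$seed <- spec$seed + 1000L
  pre <- generate_phantom(spec)
  post <- generate_phantom(post_spec)
  if (length(artifact_levels)) post <- apply_stem_artifact(post, artifact_levels)
  list(pre = pre, post = post,
       truth = list(pre_radii = r0, post_radii = post_radii,
                    delta_proximal = post_proximal_delta_mm,
                    delta_middle = post_middle_delta_mm,
                    artifact_levels = artifact_levels))
}

#' Apply a known rigid misalignment to a volume
#'
#' Resamples the volume under the stated rigid transform (rotation about
#' the volume centre, then translation) with nearest-neighbour
#' interpolation, as appropriate for label images. The output grid is
#' enlarged to contain the transformed volume, so no labelled voxel is
#' pushed outside the grid. The generating transform is attached as the
#' `true_transform` attribute for oracle use.
#'
#' By default the output grid is at half the input voxel pitch
#' (`supersample = 2`): same-pitch nearest-neighbour resampling
#' re-quantises the label boundary a second time, and that double
#' quantisation — not the orientation recovery this operator is used to
#' probe — would otherwise dominate downstream centroid noise. A finer
#' output grid represents the one frozen input boundary faithfully, at the
#' cost of `supersample^3` times the voxel count; `supersample = 1` gives
#' the plain same-grid resample.
#'
#' @param volume A [labeled_volume()].
#' @param rotation_deg Length-3 rotations (degrees) about the x, y, z axes,
#'   each within +/-30.
#' @param translation_mm Length-3 translation (mm).
#' @param supersample Output grid refinement factor (>= 1).
#' @return The resampled [labeled_volume()].
#' @export
apply_rigid_misalignment <- function(volume, rotation_deg,
                                     translation_mm = c(0, 0, 0),
                                     supersample = 2) {
  if (any(abs(rotation_deg) > 30))
    stop("misalignment angles must lie within +/-30 degrees")
  if (supersample < 1) stop("supersample must be >= 1")
  rot <- rotation_xyz(rotation_deg)
  dims <- dim(volume$voxels)
  ctr <- volume$origin + (dims - 1) * volume$spacing / 2
  tf <- rigid_transform(rot, drop(translation_mm + ctr - rot %*% ctr))
  if (rotation_angle_deg(rot) < 1e-12 && all(translation_mm == 0)) {
    attr(volume, "true_transform") <- tf
    return(volume)
  }
  corners <- as.matrix(expand.grid(
    x = volume$origin[1] + c(0, dims[1] - 1) * volume$spacing[1],
    y = volume$origin[2] + c(0, dims[2] - 1) * volume$spacing[2],
    z = volume$origin[3] + c(0, dims[3] - 1) * volume$spacing[3]))
  tc <- apply_rigid(tf, corners)
  lo <- apply(tc, 2, min); hi <- apply(tc, 2, max)
  sp <- volume$spacing / supersample
  ndims <- pmax(1L, ceiling((hi - lo) / sp)) + 1L
  inv <- invert_rigid(tf)
  xs <- lo[1] + (seq_len(ndims[1]) - 1) * sp[1]
  ys <- lo[2] + (seq_len(ndims[2]) - 1) * sp[2]
  xmat <- matrix(xs, ndims[1], ndims[2])
  ymat <- matrix(ys, ndims[1], ndims[2], byrow = TRUE)
  ri <- inv$rotation; ti <- inv$translation
  out <- array(0L, dim = ndims)
  for (k in seq_len(ndims[3])) {
    zsc <- lo[3] + (k - 1) * sp[3]
    px <- ri[1, 1] * xmat + ri[1, 2] * ymat + ri[1, 3] * zsc + ti[1]
    py <- ri[2, 1] * xmat + ri[2, 2] * ymat + ri[2, 3] * zsc + ti[2]
    pz <- ri[3, 1] * xmat + ri[3, 2] * ymat + ri[3, 3] * zsc + ti[3]
    i <- as.integer(round((px - volume$origin[1]) / volume$spacing[1])) + 1L
    j <- as.integer(round((py - volume$origin[2]) / volume$spacing[2])) + 1L
    kk <- as.integer(round((pz - volume$origin[3]) / volume$spacing[3])) + 1L
    ok <- i >= 1L & i <= dims[1] & j >= 1L & j <= dims[2] &
          kk >= 1L & kk <= dims[3]
    vals <- integer(length(i))
    vals[ok] <- volume$voxels[cbind(i[ok], j[ok], kk[ok])]
    out[, , k] <- vals
  }
  res <- labeled_volume(out, sp, lo, volume$label_map)
  attr(res, "ground_truth") <- attr(volume, "ground_truth")
  attr(res, "true_transform") <- tf
  res
}

#' Cohort specification for paired pre/post studies
#'
#' Encodes the statistical structure the paired analysis assumes: treated
#' femurs change their proximal (and optionally middle) arc radius between
#' the two scans while control femurs change by `control_effect_mm`;
#' between-patient variation of the baseline radius, shared digitisation
#' jitter per scan, and independent per-observer tracing jitter.
#'
#' Noise amplitudes are half-widths of uniform centroid perturbations
#' (mm). The defaults are matched to the per-level centroid uncertainty of
#' 1 mm voxel acquisitions, and propagate to a within-pair radius noise of
#' roughly 20 mm SD at R = 1000 mm (amplification 8R^2/L^2 with L =
#' 100 mm).
#'
#' @param n_patients Number of patients (>= 1).
#' @param proximal_effect_mm Mean radius change applied to the treated
#'   femur's proximal region at follow-up (mm; negative = increased bow).
#' @param middle_effect_mm Treated-side middle-region change (mm).
#' @param control_effect_mm Radius change on the untreated side (mm),
#'   applied to proximal and middle regions (ageing drift).
#' @param between_patient_sd_mm SD of the per-patient baseline radius about
#'   the template (mm).
#' @param observer_noise_mm Independent per-observer centroid jitter
#'   half-width (mm).
#' @param scan_noise_mm Digitisation jitter half-width shared by both
#'   observers of one scan (mm).
#' @param artifact_levels Heights (cm) with stem artifact on treated post
#'   acquisitions (voxel output only; empty by default).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10, proximal_effect_mm = -60,
                        middle_effect_mm = 0, control_effect_mm = 0,
                        between_patient_sd_mm = 120,
                        observer_noise_mm = 0.02, scan_noise_mm = 0.03,
                        artifact_levels = numeric(0), seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (between_patient_sd_mm < 0 || observer_noise_mm < 0 || scan_noise_mm < 0)
    stop("noise SDs must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 proximal_effect_mm = proximal_effect_mm,
                 middle_effect_mm = middle_effect_mm,
                 control_effect_mm = control_effect_mm,
                 between_patient_sd_mm = between_patient_sd_mm,
                 observer_noise_mm = observer_noise_mm,
                 scan_noise_mm = scan_noise_mm,
                 artifact_levels = artifact_levels, seed = as.integer(seed)),
            class = "cohort_spec")
}

# analytic level centroids of a piecewise-arc centreline (no voxelisation)
analytic_centroids <- function(region_radii, direction, layout) {
  cl <- make_centerline(region_radii, direction, layout)
  z <- LEVEL_HEIGHTS_CM * 10
  data.frame(height_cm = LEVEL_HEIGHTS_CM, x_ml_mm = 0,
             y_ap_mm = cl$fy(z), z_si_mm = z, quality = "clean")
}

#' Generate a paired synthetic cohort
#'
#' Produces, per patient, treated and control femurs at pre and post
#' timepoints, each segmented by two observers — the synthetic twin of a
#' paired pre/post CT study. With `output = "centroids"` (default) the
#' level centroids are computed analytically from the generating arcs and
#' perturbed by the seeded scan/observer jitter: fast enough for Monte
#' Carlo over many cohorts. With `output = "volumes"` full phantom volumes
#' are rasterised and the observers differ by seeded boundary-erosion noise
#' of amplitude `observer_noise_mm`.
#'
#' @param spec_template A [phantom_spec()]; per-patient baseline radii are
#'   drawn around its `sagittal_radius_mm`.
#' @param cohort A [cohort_spec()].
#' @param output `"centroids"` or `"volumes"`.
#' @return A list of class `synthetic_cohort`: `series` (named list of
#'   [centroid_series()]; volumes route also returns `volumes`),
#'   `ground_truth` (data frame of generating radii and true deltas), and
#'   the two spec objects.
#' @export
generate_cohort <- function(spec_template, cohort,
                            output = c("centroids", "volumes")) {
  output <- match.arg(output)
  stopifnot(inherits(spec_template, "phantom_spec"), inherits(cohort, "cohort_spec"))
  lay <- spec_template$landmark_layout
  r0 <- spec_template$sagittal_radius_mm
  series <- list()
  volumes <- list()
  truth_rows <- list()
  with_seed(cohort$seed, {
    for (i in seq_len(cohort$n_patients)) {
      pid <- sprintf("P%02d", i)
      base <- c(treated = r0 + rnorm(1, 0, cohort$between_patient_sd_mm),
                control = r0 + rnorm(1, 0, cohort$between_patient_sd_mm))
      for (side in c("treated", "control")) {
        for (tp in c("pre", "post")) {
          radii <- rep(base[[side]], 3)
          if (tp == "post") {
            if (side == "treated") {
              radii[2] <- radii[2] + cohort$middle_effect_mm
              radii[3] <- radii[3] + cohort$proximal_effect_mm
            } else {
              radii[2] <- radii[2] + cohort$control_effect_mm
              radii[3] <- radii[3] + cohort$control_effect_mm
            }
          }
          if (output == "centroids") {
            cen <- analytic_centroids(radii, spec_template$bow_direction, lay)
            nlev <- nrow(cen)
            scan_jit <- cbind(runif(nlev, -1, 1), runif(nlev, -1, 1)) *
              cohort$scan_noise_mm
            for (obs in c("obs1", "obs2")) {
              obs_jit <- cbind(runif(nlev, -1, 1), runif(nlev, -1, 1)) *
                cohort$observer_noise_mm
              cen_o <- cen
              cen_o$x_ml_mm <- cen$x_ml_mm + scan_jit[, 1] + obs_jit[, 1]
              cen_o$y_ap_mm <- cen$y_ap_mm + scan_jit[, 2] + obs_jit[, 2]
              series[[paste(pid, side, tp, obs, sep = ".")]] <-
                centroid_series(pid, side, tp, obs, cen_o)
            }
          } else {
            sp <- spec_template
            sp$region_radii_mm <- radii
            sp$seed <- spec_template$seed + 17L * i +
              4L * (side == "control") + 2L * (tp == "post")
            vol <- generate_phantom(sp)
            if (side == "treated" && tp == "post" &&
                length(cohort$artifact_levels))
              vol <- apply_stem_artifact(vol, cohort$artifact_levels)
            volumes[[paste(pid, side, tp, sep = ".")]] <- vol
            frame <- orient_femur(vol)
            for (obs in c("obs1", "obs2")) {
              series[[paste(pid, side, tp, obs, sep = ".")]] <-
                extract_series(vol, frame, pid, side, tp, obs,
                               observer_noise_mm = cohort$observer_noise_mm,
                               noise_seed = sp$seed + (obs == "obs2"))
            }
          }
          truth_rows[[paste(pid, side, tp, sep = ".")]] <-
            data.frame(patient_id = pid, side = side, timepoint = tp,
                       R_distal = radii[1], R_middle = radii[2],
                       R_proximal = radii[3])
        }
      }
    }
  })
  gt <- do.call(rbind, truth_rows)
  rownames(gt) <- NULL
  out <- list(series = series, ground_truth = gt,
              spec_template = spec_template, cohort = cohort)
  if (output == "volumes") out$volumes <- volumes
  structure(out, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$cohort$n_patients, "patients,",
      length(x$series), "centroid series\n")
  invisible(x)
}
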