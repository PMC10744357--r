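#' Extract the canal level mask at a given height
#'
#' Selects the canal-label voxels whose oriented z lies within a thin axial
#' slab centred on the target height, then keeps the largest connected
#' component (the deterministic stand-in for manual cleaning of the level
#' segmentation). An empty slab yields a mask flagged missing rather than an
#' error; the series records the gap.
#'
#' The default slab spans 9 mm. Slab averaging suppresses the voxelisation
#' noise of a single slice, which the downstream three-point circle fit
#' amplifies by roughly `8 R^2 / L^2` (L = 100 mm triplet span); a single
#' voxel layer can be requested by setting `slab_mm` to the slice thickness.
#'
#' @param volume A [labeled_volume()].
#' @param frame A `world_frame` from [set_reference_plane()].
#' @param height_cm Level height above the reference plane, cm.
#' @param slab_mm Physical slab thickness, mm.
#' @param cloud Optional precomputed canal point cloud (internal cache used
#'   by [extract_series()] to avoid re-deriving coordinates per level).
#' @return An object of class `level_mask`: oriented voxel-centre coordinates
#'   (`coords`, mm, z measured from the reference plane), voxel indices
#'   (`ind`), `height_cm`, `pixel_area_mm2`, and flags `missing`,
#'   `components_removed`, `solidity`.
#' @export
extract_level <- function(volume, frame, height_cm, slab_mm = 9, cloud = NULL) {
  target <- height_cm * 10
  if (is.null(cloud)) cloud <- canal_cloud(volume, frame)
  pts <- cloud$pts
  idx <- cloud$ind
  sel <- abs(pts[, 3] - target) <= slab_mm / 2
  if (!any(sel)) {
    return(structure(list(height_cm = height_cm, coords = NULL, ind = NULL,
                          pixel_area_mm2 = prod(volume$spacing[1:2]),
                          missing = TRUE, components_removed = 0L,
                          solidity = NA_real_),
                     class = "level_mask"))
  }
  ind <- idx[sel, , drop = FALSE]
  coords <- pts[sel, , drop = FALSE]
  comp <- voxel_components(ind)
  keep <- comp == which.max(tabulate(comp))
  removed <- length(unique(comp)) - 1L
  ind <- ind[keep, , drop = FALSE]
  coords <- coords[keep, , drop = FALSE]
  structure(list(height_cm = height_cm, coords = coords, ind = ind,
                 pixel_area_mm2 = prod(volume$spacing[1:2]),
                 missing = FALSE, components_removed = removed,
                 solidity = mask_solidity(coords,
                                          sqrt(prod(volume$spacing[1:2])))),
            class = "level_mask")
}

#' @export
print.level_mask <- function(x, ...) {
  if (x$missing) cat("Level mask at", x$height_cm, "cm: missing\n")
  else cat("Level mask at", x$height_cm, "cm:", nrow(x$coords), "voxels",
           if (x$components_removed > 0L) "(cleaned)" else "", "\n")
  invisible(x)
}

# connected components of a voxel index set; 4-connectivity within a single
# layer, 26-connectivity when the slab spans several layers (oblique slabs).
# Vectorised: neighbour edges found by hashed match, then union-find.
voxel_components <- function(ind) {
  n <- nrow(ind)
  if (n == 1L) return(1L)
  single_layer <- length(unique(ind[, 3])) == 1L
  if (single_layer) {
    moves <- rbind(c(1, 0, 0), c(0, 1, 0))           # half-set; edges undirected
  } else {
    moves <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = 0:1))
    moves <- moves[moves[, 3] == 1 | (moves[, 3] == 0 &
              (moves[, 1] == 1 | (moves[, 1] == 0 & moves[, 2] == 1))), ,
              drop = FALSE]
  }
  span <- apply(ind, 2L, range)
  dims <- span[2, ] - span[1, ] + 3L
  enc <- function(m) {
    (m[, 1] - span[1, 1] + 1) + dims[1] * ((m[, 2] - span[1, 2] + 1) +
      dims[2] * (m[, 3] - span[1, 3] + 1))
  }
  codes <- enc(ind)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (m in seq_len(nrow(moves))) {
    nb <- sweep(ind, 2L, as.numeric(moves[m, ]), "+")
    hit <- match(enc(nb), codes)
    src <- which(!is.na(hit))
    for (s in src) {
      a <- find(s); b <- find(hit[s])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# ratio of in-plane footprint area to its convex hull area; crescent-shaped
# masks (prosthetic lumen erosion) fall well below 1. The footprint is
# counted on a grid at the pixel pitch so oblique (multi-layer) slabs whose
# projections overlap are not over-counted.
mask_solidity <- function(coords, pitch = 1) {
  if (is.null(coords) || nrow(coords) < 8L) return(NA_real_)
  xy <- coords[, 1:2, drop = FALSE]
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (hull_area <= 0) return(NA_real_)
  cells <- unique(paste(round(xy[, 1] / pitch), round(xy[, 2] / pitch)))
  (length(cells) * pitch^2) / hull_area
}

#' Centroid of a level mask
#'
#' The canal centroid is the geometric centre of the level segmentation: the
#' area-weighted mean of the voxel centres in the mask, in oriented world
#' coordinates (mm). The z coordinate is the mean height of the slab voxels.
#'
#' @param mask A `level_mask` from [extract_level()].
#' @return A one-row data frame (class `canal_centroid`) with columns
#'   `height_cm`, `x_ml_mm`, `y_ap_mm`, `z_si_mm`, `quality`
#'   (`"clean"`, `"artifact_cleaned"` or `"missing"`).
#' @export
centroid <- function(mask) {
  if (mask$missing || is.null(mask$coords) || nrow(mask$coords) == 0L)
    stop("cannot compute the centroid of an empty level mask; ",
         "filter missing levels first")
  m <- colMeans(mask$coords)
  quality <- if (mask$components_removed > 0L ||
                 (!is.na(mask$solidity) && mask$solidity < 0.9))
    "artifact_cleaned" else "clean"
  structure(data.frame(height_cm = mask$height_cm, x_ml_mm = m[1],
                       y_ap_mm = m[2], z_si_mm = m[3], quality = quality,
                       row.names = NULL),
            class = c("canal_centroid", "data.frame"))
}

#' Centroid series for one femur at one timepoint
#'
#' @param patient_id Patient identifier.
#' @param side `"treated"` or `"control"`.
#' @param timepoint `"pre"` or `"post"`.
#' @param observer Observer identifier.
#' @param centroids Data frame with columns `height_cm`, `x_ml_mm`,
#'   `y_ap_mm`, `z_si_mm`, `quality`; heights must come from the canonical
#'   seven-level set and be unique. Missing levels are padded with NA rows
#'   flagged `"missing"` and the series is marked incomplete.
#' @return An object of class `centroid_series`.
#' @export
centroid_series <- function(patient_id, side, timepoint, observer, centroids) {
  centroids <- as.data.frame(centroids)
  for (col in c("height_cm", "x_ml_mm", "y_ap_mm", "z_si_mm"))
    centroids[[col]] <- as.numeric(centroids[[col]])
  if (any(!centroids$height_cm %in% LEVEL_HEIGHTS_CM))
    stop("heights must be drawn from the canonical set: ",
         paste(LEVEL_HEIGHTS_CM, collapse = ", "))
  if (anyDuplicated(centroids$height_cm))
    stop("duplicate level heights in centroid series")
  pad <- setdiff(LEVEL_HEIGHTS_CM, centroids$height_cm)
  if (length(pad)) {
    centroids <- rbind(centroids,
                       data.frame(height_cm = pad, x_ml_mm = NA_real_,
                                  y_ap_mm = NA_real_, z_si_mm = NA_real_,
                                  quality = "missing"))
  }
  centroids$quality[is.na(centroids$y_ap_mm)] <- "missing"
  centroids <- centroids[order(centroids$height_cm), , drop = FALSE]
  rownames(centroids) <- NULL
  structure(list(patient_id = patient_id, side = side, timepoint = timepoint,
                 observer = observer, centroids = centroids,
                 complete = !any(centroids$quality == "missing")),
            class = "centroid_series")
}

#' @export
as.data.frame.centroid_series <- function(x, ...) {
  cbind(data.frame(patient_id = x$patient_id, side = x$side,
                   timepoint = x$timepoint, observer = x$observer),
        x$centroids)
}

#' @export
print.centroid_series <- function(x, ...) {
  cat("Centroid series:", x$patient_id, x$side, x$timepoint,
      paste0("(observer ", x$observer, ")"),
      if (x$complete) "- complete" else "- incomplete", "\n")
  print(x$centroids)
  invisible(x)
}

#' Extract the full seven-level centroid series from a volume
#'
#' Runs [extract_level()] and [centroid()] at each canonical height. Levels
#' whose slab is empty are recorded as missing; segments whose triplet
#' touches a missing level later report not-computable. Optional observer
#' noise applies a seeded directional boundary erosion to each level mask
#' before the centroid is taken (see [generate_cohort()]).
#'
#' @param volume A [labeled_volume()].
#' @param frame A `world_frame`.
#' @param patient_id,side,timepoint,observer Series metadata.
#' @param slab_mm Slab thickness passed to [extract_level()].
#' @param observer_noise_mm Amplitude of simulated segmentation-boundary
#'   noise (mm); 0 disables it.
#' @param noise_seed Seed for the observer-noise stream.
#' @return A [centroid_series()].
#' @export
extract_series <- function(volume, frame, patient_id = "anon",
                           side = "treated", timepoint = "pre",
                           observer = "obs1", slab_mm = 9,
                           observer_noise_mm = 0, noise_seed = 1L) {
  rows <- vector("list", length(LEVEL_HEIGHTS_CM))
  rng <- noise_stream(noise_seed)
  cloud <- canal_cloud(volume, frame)
  for (i in seq_along(LEVEL_HEIGHTS_CM)) {
    h <- LEVEL_HEIGHTS_CM[i]
    mask <- extract_level(volume, frame, h, slab_mm = slab_mm, cloud = cloud)
    if (observer_noise_mm > 0 && !mask$missing)
      mask <- erode_mask_boundary(mask, observer_noise_mm, rng)
    rows[[i]] <- if (mask$missing)
      data.frame(height_cm = h, x_ml_mm = NA_real_, y_ap_mm = NA_real_,
                 z_si_mm = NA_real_, quality = "missing")
    else centroid(mask)
  }
  centroid_series(patient_id, side, timepoint, observer, do.call(rbind, rows))
}

# canal voxel cloud in oriented coordinates, computed once per series
canal_cloud <- function(volume, frame) {
  list(pts = oriented_coords(volume, frame, "canal"),
       ind = which(volume$voxels == volume$label_map[["canal"]], arr.ind = TRUE),
       pixel_area = prod(volume$spacing[1:2]))
}

# small deterministic RNG stream independent of the global .Random.seed
noise_stream <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
}

# directional boundary erosion: removes the voxels lying within depth `rho`
# of the mask's extreme along a random in-plane direction, emulating an
# observer tracing slightly inside the true boundary on one side
erode_mask_boundary <- function(mask, amplitude, rng) {
  theta <- 2 * pi * rng()
  rho <- amplitude * rng()
  if (rho <= 0 || nrow(mask$coords) < 10L) return(mask)
  d <- mask$coords[, 1] * cos(theta) + mask$coords[, 2] * sin(theta)
  keep <- d <= max(d) - rho
  if (sum(keep) < 5L) return(mask)
  mask$coords <- mask$coords[keep, , drop = FALSE]
  mask$ind <- mask$ind[keep, , drop = FALSE]
  mask
}
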