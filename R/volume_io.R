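#' Labelled 3D volume
#'
#' Carrier for voxelised label masks of the femur: the medullary canal plus
#' landmark label regions (posterior condyles, greater and lesser trochanter,
#' epicondyles). The voxel grid is axis-aligned: voxel `(i, j, k)` (1-based)
#' has physical centre `origin + (c(i,j,k) - 1) * spacing`, in mm.
#'
#' @param voxels 3D integer array of label values (0 = background).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical coordinate of voxel (1,1,1) in mm.
#' @param label_map named integer vector mapping role names (see
#'   `femcurve:::CANONICAL_ROLES`) to label values.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, spacing, origin = c(0, 0, 0), label_map) {
  stopifnot(length(dim(voxels)) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("spacing components must be strictly positive")
  if (is.null(names(label_map)) || any(!nzchar(names(label_map))))
    stop("label_map must be a named vector of role -> label value")
  unknown <- setdiff(names(label_map), CANONICAL_ROLES)
  if (length(unknown))
    stop("unknown label roles: ", paste(unknown, collapse = ", "))
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 label_map = setNames(as.integer(label_map), names(label_map))),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("Labelled volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels, spacing", paste(format(x$spacing, digits = 3), collapse = " x "),
      "mm\n  roles:", paste(names(x$label_map), collapse = ", "), "\n")
  invisible(x)
}

# physical centres (n x 3, mm) of all voxels carrying the label of `role`
label_coords <- function(volume, role) {
  lab <- volume$label_map[[role]]
  if (is.null(lab)) stop("role '", role, "' not present in label_map")
  idx <- which(volume$voxels == lab, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(matrix(numeric(0), ncol = 3L))
  sweep(sweep(idx - 1, 2L, volume$spacing, "*"), 2L, volume$origin, "+")
}

label_count <- function(volume, role) {
  lab <- volume$label_map[[role]]
  if (is.null(lab)) 0L else sum(volume$voxels == lab)
}

validate_labels <- function(volume, roles = names(volume$label_map)) {
  missing <- roles[vapply(roles, function(r) label_count(volume, r) == 0L, logical(1))]
  if (length(missing))
    stop("label region(s) empty or absent from volume: ",
         paste(missing, collapse = ", "))
  invisible(volume)
}

#' Read a labelled volume from NIfTI or NRRD
#'
#' Spacing and origin are taken from the image header; the label values are
#' validated against `label_config` and a hard error names any declared role
#' whose label is absent from the volume (the canal label must always be
#' nonempty).
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @param label_config Named integer vector (or list) mapping role names to
#'   label values, e.g. `c(canal = 1, posterior_condyle_left = 2, ...)`, or a
#'   path to a YAML/JSON file holding such a mapping.
#' @return A [labeled_volume()].
#' @export
read_volume <- function(path, label_config) {
  if (!file.exists(path)) stop("file not found: ", path)
  label_config <- read_label_config(label_config)
  if (!"canal" %in% names(label_config)) stop("label_config must declare 'canal'")
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::readNifti(path)
    arr <- array(as.integer(round(as.array(img))), dim = dim(img))
    spacing <- abs(RNifti::pixdim(img))[1:3]
    origin <- tryCatch({
      xf <- RNifti::xform(img)
      as.numeric(xf[1:3, 4])
    }, error = function(e) c(0, 0, 0))
    vol <- labeled_volume(arr, spacing, origin, label_config)
  } else if (grepl("\\.nrrd$", low)) {
    nr <- read_nrrd(path)
    vol <- labeled_volume(nr$data, nr$spacing, nr$origin, label_config)
  } else {
    stop("unsupported format (expected .nii, .nii.gz or .nrrd): ", path)
  }
  validate_labels(vol)
  vol
}

#' Write a labelled volume to NIfTI or NRRD
#'
#' @param volume A [labeled_volume()].
#' @param path Output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::asNifti(volume$voxels, internal = FALSE)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::qform(img) <- structure(rbind(cbind(diag(volume$spacing), volume$origin),
                                          c(0, 0, 0, 1)), code = 2L)
    RNifti::writeNifti(img, path, datatype = "int16")
  } else if (grepl("\\.nrrd$", low)) {
    write_nrrd(volume$voxels, path, spacing = volume$spacing, origin = volume$origin)
  } else {
    stop("unsupported format (expected .nii, .nii.gz or .nrrd): ", path)
  }
  invisible(path)
}

#' Read a label role -> value mapping from YAML or JSON
#'
#' @param x A named vector/list (returned as-is after validation) or a path to
#'   a `.yaml`/`.yml`/`.json` file.
#' @return Named integer vector.
#' @export
read_label_config <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- if (grepl("\\.json$", tolower(x))) jsonlite::read_json(x, simplifyVector = TRUE)
         else yaml::read_yaml(x)
  }
  x <- unlist(x)
  if (is.null(names(x))) stop("label config must map role names to label values")
  setNames(as.integer(x), names(x))
}

CENTROID_COLUMNS <- c("patient_id", "side", "timepoint", "observer",
                      "height_cm", "x_ml_mm", "y_ap_mm", "z_si_mm", "quality")

#' Write a centroid series to CSV
#'
#' Columns: patient_id, side, timepoint, observer, height_cm, x_ml_mm,
#' y_ap_mm, z_si_mm, quality. Coordinates are written with six decimal
#' places, so a write/read round trip preserves them at that precision.
#'
#' @param series A [centroid_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(series, path) {
  df <- as.data.frame(series)
  for (col in c("x_ml_mm", "y_ap_mm", "z_si_mm"))
    df[[col]] <- sprintf("%.6f", df[[col]])
  df[df == "NA"] <- ""
  write.csv(df[, CENTROID_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a centroid series from CSV
#'
#' A series missing some of the seven canonical levels is flagged incomplete
#' (`complete = FALSE`) but loads; segment fits whose triplet touches a
#' missing level later report not-computable. A malformed or empty file is a
#' parse error.
#'
#' @param path CSV path as written by [write_centroids()].
#' @return A [centroid_series()].
#' @export
read_centroids <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty centroid file: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed centroid CSV (", path, "): ",
                                          conditionMessage(e)))
  missing_cols <- setdiff(CENTROID_COLUMNS, names(df))
  if (length(missing_cols))
    stop("malformed centroid CSV, missing column(s) at line 1: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("empty centroid file (header only): ", path)
  bad <- which(!df$height_cm %in% LEVEL_HEIGHTS_CM)
  if (length(bad))
    stop("malformed centroid CSV at line ", bad[1] + 1L,
         ": height_cm must be one of ", paste(LEVEL_HEIGHTS_CM, collapse = ", "))
  centroid_series(patient_id = df$patient_id[1], side = df$side[1],
                  timepoint = df$timepoint[1], observer = df$observer[1],
                  centroids = df[, c("height_cm", "x_ml_mm", "y_ap_mm",
                                     "z_si_mm", "quality")])
}
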