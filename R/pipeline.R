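#' Measure one femur end to end
#'
#' Orients the volume (posterior tangency fit + reference plane), extracts
#' the seven-level centroid series, and computes the four segment radii.
#'
#' @param volume A [labeled_volume()] (or a path readable by
#'   [read_volume()] when `label_config` is given).
#' @param label_config Label role mapping, only used when `volume` is a path.
#' @param patient_id,side,timepoint,observer Series metadata.
#' @param slab_mm Level slab thickness (mm), see [extract_level()].
#' @return List with `frame`, `eligibility`, `series`, `radii`.
#' @export
measure_femur <- function(volume, label_config = NULL, patient_id = "anon",
                          side = "treated", timepoint = "pre",
                          observer = "obs1", slab_mm = 9) {
  if (is.character(volume)) volume <- read_volume(volume, label_config)
  frame <- orient_femur(volume)
  elig <- tryCatch(eligibility_length(volume, frame), error = function(e) NULL)
  series <- extract_series(volume, frame, patient_id, side, timepoint,
                           observer, slab_mm = slab_mm)
  list(frame = frame, eligibility = elig, series = series,
       radii = segment_radii(series))
}

#' Long-format radius table
#'
#' Flattens a list of [segment_radii()] objects into one row per femur,
#' timepoint and segment, the layout consumed by the cohort statistics.
#'
#' @param radii_list List of `segment_radii`.
#' @return Data frame with columns `patient_id`, `side`, `timepoint`,
#'   `observer`, `segment`, `R_mm` (NA when not computable or degenerate),
#'   `direction`.
#' @export
radii_table <- function(radii_list) {
  rows <- lapply(radii_list, function(sr) {
    do.call(rbind, lapply(names(SEGMENT_TRIPLETS), function(seg) {
      fit <- sr[[seg]]
      ok <- is_computable(fit)
      data.frame(patient_id = sr$patient_id, side = sr$side,
                 timepoint = sr$timepoint, observer = sr$observer,
                 segment = seg,
                 R_mm = if (ok) fit$R else NA_real_,
                 direction = if (ok) fit$direction else NA_character_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-patient radius changes for both sides
#'
#' From a long radius table holding both timepoints of both sides, computes
#' per patient and segment the prosthetic-side change `delta_P` and the
#' control-side change `delta_C` (post minus pre, mm). Pairs with a missing
#' radius at either timepoint give NA.
#'
#' @param radii Long table from [radii_table()] (a single observer).
#' @return Data frame with columns `patient_id`, `segment`, `delta_P`,
#'   `delta_C`.
#' @export
compute_deltas <- function(radii) {
  pick <- function(pid, side, tp, seg) {
    v <- radii$R_mm[radii$patient_id == pid & radii$side == side &
                    radii$timepoint == tp & radii$segment == seg]
    if (length(v) == 1L) v else NA_real_
  }
  out <- expand.grid(patient_id = unique(radii$patient_id),
                     segment = names(SEGMENT_TRIPLETS),
                     stringsAsFactors = FALSE)
  out$delta_P <- mapply(function(p, s)
    pick(p, "treated", "post", s) - pick(p, "treated", "pre", s),
    out$patient_id, out$segment)
  out$delta_C <- mapply(function(p, s)
    pick(p, "control", "post", s) - pick(p, "control", "pre", s),
    out$patient_id, out$segment)
  out
}

#' Run the full paired cohort analysis
#'
#' Mirrors the study design end to end: segment radii per femur, timepoint
#' and observer; inter-observer reliability screen (unreliable or
#' indeterminate segments are excluded); baseline treated-vs-control
#' comparison; and the headline paired comparison of the radius changes
#' delta_P vs delta_C on the reliable segments. The substantive analysis
#' uses observer 1; observer 2 enters only the reliability screen.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or a plain
#'   list of [centroid_series()].
#' @param alpha Significance threshold for every test.
#' @return List of class `cohort_analysis`: `radii` (long table, both
#'   observers), `interobserver`, `reliable_segments`, `baseline`, `delta`
#'   (named lists of `stat_result` per reliable segment), `deltas` (the
#'   per-patient changes), `excluded` (reversed/ineligible femurs, if any).
#' @export
analyze_cohort <- function(cohort, alpha = 0.05) {
  series <- if (inherits(cohort, "synthetic_cohort")) cohort$series else cohort
  radii_all <- radii_table(lapply(series, segment_radii))
  # reversed-curvature screen on baseline observer-1 series
  reversed <- vapply(series, function(s) {
    if (s$observer == "obs1" && s$timepoint == "pre")
      isTRUE(reversed_curvature_screen(s)$reversed)
    else FALSE
  }, logical(1))
  excluded <- unique(vapply(series[reversed], function(s) s$patient_id,
                            character(1)))
  if (length(excluded))
    radii_all <- radii_all[!radii_all$patient_id %in% excluded, , drop = FALSE]
  obs1 <- radii_all[radii_all$observer == "obs1", , drop = FALSE]
  obs2 <- radii_all[radii_all$observer == "obs2", , drop = FALSE]
  screen <- interobserver_screen(obs1, obs2, alpha = alpha)
  reliable <- screen$segment[isTRUE_vec(screen$reliable)]
  deltas <- compute_deltas(obs1)
  baseline <- list(); delta <- list()
  for (seg in reliable) {
    pre_t <- obs1[obs1$side == "treated" & obs1$timepoint == "pre" &
                  obs1$segment == seg, ]
    pre_c <- obs1[obs1$side == "control" & obs1$timepoint == "pre" &
                  obs1$segment == seg, ]
    m <- match(pre_t$patient_id, pre_c$patient_id)
    baseline[[seg]] <- baseline_comparison(pre_t$R_mm, pre_c$R_mm[m],
                                           segment = seg, alpha = alpha)
    delta[[seg]] <- delta_comparison(deltas, seg, alpha = alpha)
  }
  structure(list(radii = radii_all, interobserver = screen,
                 reliable_segments = reliable, baseline = baseline,
                 delta = delta, deltas = deltas, excluded = excluded,
                 alpha = alpha),
            class = "cohort_analysis")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Paired cohort analysis (alpha =", x$alpha, ")\n")
  if (length(x$excluded))
    cat("  excluded (reversed curvature):", paste(x$excluded, collapse = ", "), "\n")
  cat("  inter-observer screen:\n")
  print(x$interobserver, row.names = FALSE)
  cat("  reliable segments:", paste(x$reliable_segments, collapse = ", "), "\n")
  for (seg in x$reliable_segments) {
    cat("  "); print(x$baseline[[seg]])
    cat("  "); print(x$delta[[seg]])
  }
  invisible(x)
}

#' Write per-patient result records as JSON
#'
#' @param analysis A `cohort_analysis`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_analysis_json <- function(analysis, path) {
  res <- list(
    interobserver = analysis$interobserver,
    reliable_segments = analysis$reliable_segments,
    baseline = lapply(analysis$baseline, unclass),
    delta = lapply(analysis$delta, unclass),
    deltas = analysis$deltas,
    excluded = analysis$excluded)
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
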