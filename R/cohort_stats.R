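#' Paired sample for a signed-rank comparison
#'
#' Pairs containing any missing value are dropped and counted.
#'
#' @param a_values,b_values Numeric vectors of equal length (mm).
#' @param patient_ids Optional identifiers, recycled checks only.
#' @param label_a,label_b Labels for the two arms.
#' @param segment Optional segment annotation.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(a_values, b_values, patient_ids = NULL,
                          label_a = "a", label_b = "b", segment = NA_character_) {
  if (length(a_values) != length(b_values))
    stop("paired sample arms must have equal length")
  if (is.null(patient_ids)) patient_ids <- seq_along(a_values)
  keep <- is.finite(a_values) & is.finite(b_values)
  structure(list(patient_ids = patient_ids[keep],
                 a_values = as.numeric(a_values[keep]),
                 b_values = as.numeric(b_values[keep]),
                 n_dropped = sum(!keep),
                 label_a = label_a, label_b = label_b, segment = segment),
            class = "paired_sample")
}

stat_result <- function(segment, comparison, n_pairs, statistic, p, alpha,
                        method, low_power = FALSE, note = NULL) {
  structure(list(segment = segment, comparison = comparison,
                 n_pairs = n_pairs, statistic = statistic, p = p,
                 significant = is.finite(p) && p < alpha, alpha = alpha,
                 method = method, low_power = low_power, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s comparison%s: n = %d, V = %s, p = %.4g (%s at alpha = %g)%s\n",
              x$comparison,
              if (is.na(x$segment)) "" else paste0(" [", x$segment, "]"),
              x$n_pairs, format(x$statistic), x$p,
              if (x$significant) "significant" else "not significant",
              x$alpha,
              if (x$low_power) " [low power]" else ""))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided signed-rank test on the paired differences. The exact null
#' distribution is used when there are at most 25 informative pairs with no
#' ties and no zero differences; otherwise a normal approximation with tie
#' correction and continuity correction is used. Zero differences are
#' handled by the Pratt rule by default: zeros participate in the ranking,
#' then their ranks are discarded from the statistic (with the matching
#' reduction of the null mean and variance). `zero_method = "wilcox"` drops
#' zeros before ranking instead.
#'
#' All differences zero gives p = 1 with a warning; fewer than 5 pairs
#' flags the result low-power.
#'
#' @param a A `paired_sample`, or the first arm as a numeric vector.
#' @param b Second arm (when `a` is a vector).
#' @param alpha Significance threshold (default 0.05).
#' @param zero_method `"pratt"` (default) or `"wilcox"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact distribution;
#'   `NULL` picks automatically. Exact is unavailable with ties or (under
#'   Pratt) zeros.
#' @param segment,comparison Annotations carried into the result.
#' @return A `stat_result` with the statistic `V` (sum of positive-signed
#'   ranks), two-sided `p`, and `significant = p < alpha`.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, alpha = 0.05,
                                 zero_method = c("pratt", "wilcox"),
                                 exact = NULL, segment = NA_character_,
                                 comparison = "paired") {
  zero_method <- match.arg(zero_method)
  if (inherits(a, "paired_sample")) {
    segment <- if (is.na(segment)) a$segment else segment
    d <- a$a_values - a$b_values
  } else {
    stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
    keep <- is.finite(a) & is.finite(b)
    d <- a[keep] - b[keep]
  }
  n_pairs <- length(d)
  if (n_pairs < 1L) stop("no complete pairs")
  low_power <- n_pairs < 5L
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(stat_result(segment, comparison, n_pairs, statistic = NA_real_,
                       p = 1, alpha = alpha, method = "degenerate",
                       low_power = low_power))
  }
  if (zero_method == "wilcox") d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  nz <- d != 0
  v <- sum(r[nz & d > 0])
  n_zero <- sum(!nz)
  has_ties <- anyDuplicated(abs(d[nz])) > 0L
  can_exact <- !has_ties && n_zero == 0L
  use_exact <- if (is.null(exact)) (n <= 25L && can_exact) else (exact && can_exact)
  if (use_exact) {
    p <- min(1, 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n)))
    method <- "exact"
  } else {
    # Pratt moments: zeros keep their ranks 1..n_zero out of the statistic
    ev <- (n * (n + 1) / 2 - n_zero * (n_zero + 1) / 2) / 2
    tie_tab <- table(abs(d[nz]))
    varv <- (n * (n + 1) * (2 * n + 1) -
             n_zero * (n_zero + 1) * (2 * n_zero + 1)) / 24 -
            sum(tie_tab^3 - tie_tab) / 48
    if (varv <= 0) {
      p <- 1
      method <- "degenerate"
    } else {
      z <- (v - ev - 0.5 * sign(v - ev)) / sqrt(varv)
      p <- min(1, 2 * pnorm(-abs(z)))
      method <- "normal approximation (tie/zero corrected)"
    }
  }
  stat_result(segment, comparison, n_pairs, statistic = v, p = p,
              alpha = alpha, method = method, low_power = low_power)
}

#' Inter-observer reliability screen
#'
#' Compares the two observers' radii per segment with the paired
#' signed-rank test; a segment whose observers differ at `p < alpha` is
#' marked unreliable and excluded from downstream analysis (the post-hoc
#' rule that removed the distal and total radii in the motivating study).
#' Segments with fewer than 5 comparable pairs are indeterminate
#' (`reliable = NA`) and likewise excluded, with the reason recorded.
#'
#' @param obs1,obs2 Long radius tables as produced by [radii_table()]
#'   (columns `patient_id`, `side`, `timepoint`, `segment`, `R_mm`), one per
#'   observer, covering the same femurs and timepoints.
#' @param alpha Significance threshold.
#' @return Data frame with one row per segment: `segment`, `n_pairs`,
#'   `statistic`, `p`, `reliable`, `reason`.
#' @export
interobserver_screen <- function(obs1, obs2, alpha = 0.05) {
  key <- function(df) paste(df$patient_id, df$side, df$timepoint, df$segment)
  k1 <- key(obs1); k2 <- key(obs2)
  unmatched <- c(setdiff(k1, k2), setdiff(k2, k1))
  if (length(unmatched))
    stop("observer tables are misaligned; unmatched femur measurements: ",
         paste(unique(unmatched), collapse = "; "))
  m <- match(k1, k2)
  out <- lapply(names(SEGMENT_TRIPLETS), function(seg) {
    sel <- obs1$segment == seg
    a <- obs1$R_mm[sel]
    b <- obs2$R_mm[m][sel]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 5L)
      return(data.frame(segment = seg, n_pairs = sum(ok),
                        statistic = NA_real_, p = NA_real_, reliable = NA,
                        reason = "fewer than 5 comparable pairs"))
    if (all(a[ok] == b[ok]))
      return(data.frame(segment = seg, n_pairs = sum(ok),
                        statistic = NA_real_, p = 1, reliable = TRUE,
                        reason = NA_character_))
    res <- wilcoxon_signed_rank(a[ok], b[ok], alpha = alpha, segment = seg,
                                comparison = "interobserver")
    data.frame(segment = seg, n_pairs = res$n_pairs, statistic = res$statistic,
               p = res$p, reliable = !res$significant,
               reason = if (res$significant)
                 "significant inter-observer difference" else NA_character_)
  })
  do.call(rbind, out)
}

#' Baseline treated-vs-control comparison
#'
#' Paired signed-rank test of the pre-operative radii of the treated femur
#' against the untreated (control) femur, per segment: the preliminary
#' symmetry check run before any change analysis.
#'
#' @param pre_treated,pre_control Numeric vectors of per-patient baseline
#'   radii (mm) for one segment, aligned by patient.
#' @param segment Segment name (annotation).
#' @param alpha Significance threshold.
#' @return A `stat_result`.
#' @export
baseline_comparison <- function(pre_treated, pre_control,
                                segment = NA_character_, alpha = 0.05) {
  wilcoxon_signed_rank(pre_treated, pre_control, alpha = alpha,
                       segment = segment, comparison = "baseline")
}

#' Paired comparison of radius changes: prosthetic vs control femur
#'
#' The headline comparison of the study design: per patient, the change in
#' radius of curvature on the prosthetic side (delta_P = R_P,post -
#' R_P,pre) is paired with the change on the contralateral untreated side
#' (delta_C), and the two are compared with the Wilcoxon signed-rank test.
#'
#' @param deltas Data frame with columns `patient_id`, `segment`, `delta_P`,
#'   `delta_C` (mm), as produced by [compute_deltas()].
#' @param segment Segment to test.
#' @param alpha Significance threshold.
#' @return A `stat_result`.
#' @export
delta_comparison <- function(deltas, segment, alpha = 0.05) {
  segment <- match.arg(segment, names(SEGMENT_TRIPLETS))
  sel <- deltas$segment == segment
  wilcoxon_signed_rank(deltas$delta_P[sel], deltas$delta_C[sel],
                       alpha = alpha, segment = segment, comparison = "delta")
}
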