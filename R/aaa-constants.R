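# Shared constants (loaded first).

CANONICAL_ROLES <- c("canal", "posterior_condyle_left", "posterior_condyle_right",
                     "greater_trochanter", "lesser_trochanter",
                     "epicondyle_medial", "epicondyle_lateral")

#' Canonical level heights (cm above the reference axial plane)
#' @export
LEVEL_HEIGHTS_CM <- c(5, 10, 15, 20, 25, 30, 35)

# canonical centroid triplet per femoral segment (heights in cm)
SEGMENT_TRIPLETS <- list(distal = c(5, 10, 15), middle = c(15, 20, 25),
                         proximal = c(25, 30, 35), total = c(5, 20, 35))

PHANTOM_LABELS <- setNames(1:7, CANONICAL_ROLES)

`%||%` <- function(a, b) if (is.null(a)) b else a
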