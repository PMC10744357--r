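# Shared fixtures, all generated in code.

# coarse fast phantom for unit tests (2 mm voxels unless stated)
quick_phantom <- function(radius = 900, voxel = 2, seed = 11, ...) {
  generate_phantom(phantom_spec(sagittal_radius_mm = radius, voxel_mm = voxel,
                                seed = seed, ...))
}

measure_segments <- function(vol, slab_mm = 9) {
  frame <- orient_femur(vol)
  sr <- segment_radii(extract_series(vol, frame, slab_mm = slab_mm))
  vapply(c("distal", "middle", "proximal", "total"),
         function(s) if (is_computable(sr[[s]])) sr[[s]]$R else NA_real_,
         numeric(1))
}

# independent circumcircle oracle: perpendicular bisectors as a 2x2 linear
# system solved with solve(); used only to cross-check circumcircle()
bisector_circumcircle <- function(p1, p2, p3) {
  m1 <- (p1 + p2) / 2; m2 <- (p2 + p3) / 2
  d1 <- p2 - p1; d2 <- p3 - p2
  a <- rbind(d1, d2)
  b <- c(sum(d1 * m1), sum(d2 * m2))
  ctr <- solve(a, b)
  list(centre = ctr, R = sqrt(sum((p1 - ctr)^2)))
}

# brute-force exact two-sided signed-rank p-value by enumerating all 2^n
# sign assignments (no ties, no zeros)
enumerate_signrank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  ev <- n * (n + 1) / 4
  min(1, sum(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9) / 2^n)
}

# hand-built single-layer level mask from a logical 2D pixel matrix
mask_from_matrix <- function(px, height_cm = 20, spacing = 1, centre = c(0, 0)) {
  idx <- which(px, arr.ind = TRUE)
  coords <- cbind((idx[, 1] - (nrow(px) + 1) / 2) * spacing + centre[1],
                  (idx[, 2] - (ncol(px) + 1) / 2) * spacing + centre[2],
                  height_cm * 10)
  structure(list(height_cm = height_cm, coords = coords,
                 ind = cbind(idx, 1L), pixel_area_mm2 = spacing^2,
                 missing = FALSE, components_removed = 0L,
                 solidity = femcurve:::mask_solidity(coords, spacing)),
            class = "level_mask")
}

disc_matrix <- function(r, n = 2 * ceiling(r) + 5, centre = c(0, 0)) {
  xs <- (seq_len(n) - (n + 1) / 2)
  outer(xs - centre[1], xs - centre[2], function(a, b) a^2 + b^2 <= r^2)
}
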