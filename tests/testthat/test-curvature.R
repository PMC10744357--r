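test_that("circumcircle is exact on symmetric points and flags collinearity", {
  fit <- circumcircle(c(0, 1), c(1, 0), c(0, -1))
  expect_equal(fit$yC, 0)
  expect_equal(fit$zC, 0)
  expect_equal(fit$R, 1)
  expect_false(fit$degenerate)

  deg <- circumcircle(c(0, 0), c(1, 0), c(2, 0))
  expect_true(deg$degenerate)
  expect_identical(deg$R, Inf)

  expect_error(circumcircle(c(0, 0), c(0, 0), c(1, 1)), "coincident")
})

test_that("circumcircle matches the perpendicular-bisector oracle on an arc", {
  # points sampled at z = 250, 300, 350 mm from an arc of radius 900 mm
  zc <- 180; yc <- -850
  z <- c(250, 300, 350)
  y <- yc + sqrt(900^2 - (z - zc)^2)
  fit <- circumcircle(c(y[1], z[1]), c(y[2], z[2]), c(y[3], z[3]))
  expect_equal(fit$R, 900, tolerance = 1e-9)
  oracle <- bisector_circumcircle(c(y[1], z[1]), c(y[2], z[2]), c(y[3], z[3]))
  expect_equal(fit$R, oracle$R, tolerance = 1e-9)
  expect_equal(c(fit$yC, fit$zC), unname(oracle$centre), tolerance = 1e-6)
  # all three points lie at distance R from the centre
  d <- sqrt((y - fit$yC)^2 + (z - fit$zC)^2)
  expect_lt(max(abs(d - fit$R)), 1e-6)
})

test_that("centre x-coordinate agrees with the slope-form equation", {
  # the slope-form first-coordinate equation:
  # xC = (m1 m2 (y1 - y3) + m2 (x1 + x2) - m1 (x2 + x3)) / (2 (m2 - m1))
  set.seed(4)
  for (i in 1:50) {
    p <- matrix(rnorm(6, sd = 50), ncol = 2)
    m1 <- (p[2, 2] - p[1, 2]) / (p[2, 1] - p[1, 1])
    m2 <- (p[3, 2] - p[2, 2]) / (p[3, 1] - p[2, 1])
    if (!is.finite(m1) || !is.finite(m2) || abs(m2 - m1) < 1e-6) next
    xc_slope <- (m1 * m2 * (p[1, 2] - p[3, 2]) + m2 * (p[1, 1] + p[2, 1]) -
                 m1 * (p[2, 1] + p[3, 1])) / (2 * (m2 - m1))
    fit <- circumcircle(p[1, ], p[2, ], p[3, ])
    if (fit$degenerate) next
    expect_equal(fit$yC, xc_slope, tolerance = 1e-6)
  }
})

test_that("circumcircle R is invariant under rigid motion and scales linearly", {
  set.seed(9)
  for (i in 1:20) {
    p <- matrix(rnorm(6, sd = 30), ncol = 2)
    fit <- circumcircle(p[1, ], p[2, ], p[3, ])
    if (fit$degenerate) next
    th <- runif(1, 0, 2 * pi); tr <- rnorm(2, sd = 500)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    q <- p %*% t(rot) + rep(tr, each = 3)
    fit2 <- circumcircle(q[1, ], q[2, ], q[3, ])
    expect_equal(fit2$R, fit$R, tolerance = 1e-9)
    k <- runif(1, 0.1, 10)
    fit3 <- circumcircle(k * p[1, ], k * p[2, ], k * p[3, ])
    expect_equal(fit3$R, k * fit$R, tolerance = 1e-9)
  }
})

arc_series <- function(R = 1000, yc = NULL, zc = 200, direction = 1,
                       patient = "P01", side = "treated", tp = "pre") {
  if (is.null(yc)) yc <- 45 - direction * R
  z <- LEVEL_HEIGHTS_CM * 10
  y <- yc + direction * sqrt(R^2 - (z - zc)^2)
  centroid_series(patient, side, tp, "obs1",
                  data.frame(height_cm = LEVEL_HEIGHTS_CM, x_ml_mm = 0,
                             y_ap_mm = y, z_si_mm = z, quality = "clean"))
}

test_that("segment fits use the canonical triplets", {
  ser <- arc_series(R = 800)
  expect_equal(segment_radius(ser, "distal")$heights_cm, c(5, 10, 15))
  expect_equal(segment_radius(ser, "middle")$heights_cm, c(15, 20, 25))
  expect_equal(segment_radius(ser, "proximal")$heights_cm, c(25, 30, 35))
  expect_equal(segment_radius(ser, "total")$heights_cm, c(5, 20, 35))
  for (seg in c("distal", "middle", "proximal", "total"))
    expect_equal(segment_radius(ser, seg)$R, 800, tolerance = 1e-9)
  expect_error(segment_radius(ser, "shaft"), "arg")
})

test_that("a missing level disables only the segments that use it", {
  ser <- arc_series()
  ser$centroids[ser$centroids$height_cm == 10, c("y_ap_mm", "z_si_mm")] <- NA
  ser$centroids$quality[ser$centroids$height_cm == 10] <- "missing"
  expect_s3_class(segment_radius(ser, "distal"), "not_computable")
  for (seg in c("middle", "proximal", "total"))
    expect_false(inherits(segment_radius(ser, seg), "not_computable"))
})

test_that("delta radius is post minus pre with sign preserved", {
  pre <- segment_radii(arc_series(R = 1000))
  post <- segment_radii(arc_series(R = 950, tp = "post"))
  d <- delta_radius(pre, post, "proximal")
  expect_equal(d$delta_mm, -50, tolerance = 1e-6)
  same <- delta_radius(pre, segment_radii(arc_series(R = 1000, tp = "post")),
                       "middle")
  expect_equal(same$delta_mm, 0, tolerance = 1e-9)
  # not-computable propagates to an undefined delta
  broken <- arc_series(R = 950, tp = "post")
  broken$centroids[broken$centroids$height_cm == 30, "y_ap_mm"] <- NA
  broken$centroids$quality[broken$centroids$height_cm == 30] <- "missing"
  d2 <- delta_radius(pre, segment_radii(broken), "proximal")
  expect_true(is.na(d2$delta_mm))
  expect_match(d2$reason, "not computable")
  expect_error(delta_radius(pre, segment_radii(arc_series(side = "control")),
                            "distal"), "same patient")
})

test_that("reversed-curvature screen distinguishes bow directions", {
  expect_false(reversed_curvature_screen(arc_series(direction = 1))$reversed)
  expect_true(reversed_curvature_screen(arc_series(direction = -1))$reversed)
  straight <- centroid_series("P01", "treated", "pre", "obs1",
    data.frame(height_cm = LEVEL_HEIGHTS_CM, x_ml_mm = 0, y_ap_mm = 40,
               z_si_mm = LEVEL_HEIGHTS_CM * 10, quality = "clean"))
  scr <- reversed_curvature_screen(straight)
  expect_true(is.na(scr$reversed))
  expect_match(scr$reason, "degenerate")
})
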