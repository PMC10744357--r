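test_that("exact signed-rank p matches full 2^n enumeration (n <= 8)", {
  set.seed(31)
  for (n in 5:8) {
    for (rep in 1:10) {
      d <- round(rnorm(n, sd = 10), 3)
      while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n, sd = 10), 3)
      res <- wilcoxon_signed_rank(d, rep(0, n))
      expect_equal(res$p, enumerate_signrank_p(d), tolerance = 1e-12,
                   info = paste("n =", n))
      expect_identical(res$method, "exact")
    }
  }
})

test_that("all-positive unit differences give the textbook exact p", {
  # pairs (2,1),(3,2),...,(7,6): six differences of +1 -> p = 2/2^6
  a <- 2:7; b <- 1:6
  # constant differences are ties, so force exact via distinct magnitudes
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6) + 0.001 * (1:6), rep(0, 6))
  expect_equal(res$p, 0.03125, tolerance = 1e-12)
  # the tie-corrected approximation on the constant-difference version is
  # still significant at alpha = 0.05
  res_t <- wilcoxon_signed_rank(a, b)
  expect_lt(res_t$p, 0.05)
})

test_that("signed-rank agrees with stats::wilcox.test when zero-free", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    res <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    expect_equal(unname(res$statistic), unname(ref$statistic))
  }
})

test_that("degenerate and small samples are handled", {
  expect_warning(res <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(res$p, 1)
  expect_false(res$significant)
  res2 <- suppressWarnings(wilcoxon_signed_rank(c(1, 2, 3), c(0, 1, 2)))
  expect_true(res2$low_power)
  expect_error(wilcoxon_signed_rank(numeric(0), numeric(0)))
})

test_that("Pratt zero handling keeps zeros in the ranking", {
  # d = (0, 0, 1, 2, 3): Pratt ranks zeros 1.5, 1.5 then discards them
  a <- c(5, 5, 6, 7, 8); b <- c(5, 5, 5, 5, 5)
  res <- wilcoxon_signed_rank(a, b, zero_method = "pratt")
  expect_equal(unname(res$statistic), 3 + 4 + 5)
  res_w <- wilcoxon_signed_rank(a, b, zero_method = "wilcox")
  expect_equal(unname(res_w$statistic), 1 + 2 + 3)
  expect_true(res$p <= 1 && res$p >= 0 && res_w$p <= 1)
})

obs_table <- function(R, observer = "obs1") {
  grid <- expand.grid(patient_id = sprintf("P%02d", 1:8),
                      side = c("treated", "control"),
                      timepoint = c("pre", "post"),
                      segment = c("distal", "middle", "proximal", "total"),
                      stringsAsFactors = FALSE)
  grid$observer <- observer
  grid$R_mm <- R
  grid
}

test_that("interobserver screen flags exactly the biased segment", {
  set.seed(5)
  r <- 1000 + rnorm(8 * 2 * 2 * 4, sd = 80)
  o1 <- obs_table(r, "obs1")
  o2 <- obs_table(r, "obs2")
  scr <- interobserver_screen(o1, o2)
  expect_true(all(scr$reliable))
  expect_true(all(scr$p == 1))

  o2b <- o2
  o2b$R_mm[o2b$segment == "distal"] <- o2b$R_mm[o2b$segment == "distal"] + 50
  scr2 <- interobserver_screen(o1, o2b)
  expect_false(scr2$reliable[scr2$segment == "distal"])
  expect_true(all(scr2$reliable[scr2$segment != "distal"]))

  # fewer than 5 comparable pairs -> indeterminate
  o1c <- o1; o2c <- o2
  o1c$R_mm[o1c$segment == "total"][seq(5, 32)] <- NA
  o2c$R_mm[o2c$segment == "total"][seq(5, 32)] <- NA
  scr3 <- interobserver_screen(o1c, o2c)
  expect_true(is.na(scr3$reliable[scr3$segment == "total"]))
  expect_match(scr3$reason[scr3$segment == "total"], "fewer than 5")

  expect_error(interobserver_screen(o1[-1, ], o2), "misaligned")
})

test_that("baseline and delta comparisons wrap the paired test", {
  set.seed(8)
  pre_t <- 1000 + rnorm(10, sd = 50)
  pre_c <- pre_t + rnorm(10, sd = 5)
  res <- baseline_comparison(pre_t, pre_c, segment = "proximal")
  expect_identical(res$comparison, "baseline")
  expect_true(res$p > 0 && res$p <= 1)

  deltas <- data.frame(patient_id = sprintf("P%02d", 1:10),
                       segment = "proximal",
                       delta_P = -60 + rnorm(10, sd = 10),
                       delta_C = rnorm(10, sd = 10))
  res2 <- delta_comparison(deltas, "proximal")
  expect_identical(res2$comparison, "delta")
  expect_true(res2$significant)
  ident <- data.frame(patient_id = deltas$patient_id, segment = "middle",
                      delta_P = deltas$delta_C, delta_C = deltas$delta_C)
  expect_warning(res3 <- delta_comparison(ident, "middle"), "zero")
  expect_equal(res3$p, 1)
})

test_that("delta comparison is invariant to per-patient constants", {
  set.seed(13)
  deltas <- data.frame(patient_id = 1:10, segment = "proximal",
                       delta_P = rnorm(10, -40, 15), delta_C = rnorm(10, 0, 15))
  shift <- rnorm(10, sd = 100)
  shifted <- deltas
  shifted$delta_P <- deltas$delta_P + shift
  shifted$delta_C <- deltas$delta_C + shift
  expect_equal(delta_comparison(deltas, "proximal")$p,
               delta_comparison(shifted, "proximal")$p, tolerance = 1e-12)
})
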