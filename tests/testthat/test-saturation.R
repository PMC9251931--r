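test_that("spearman_rho reproduces the hand-computed rank formula", {
  # ranks of y against x: d = (1, -1, 1, -1); 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)  # monotone transform
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("spearman_rho is invariant under monotone transforms of inputs", {
  set.seed(7)
  x <- rlnorm(40); y <- x + rnorm(40, sd = 0.5)
  expect_equal(spearman_rho(x, y), spearman_rho(log(x), y))
  expect_equal(spearman_rho(x, y), spearman_rho(rank(x), rank(y)))
})

test_that("loess fit reproduces collinear data and validates inputs", {
  x <- seq(1, 10)
  y <- 3 + 2 * x
  fit <- loess_fit(x, y, span = 0.6)
  expect_equal(predict(fit, x), y, tolerance = 1e-12)
  expect_equal(predict(fit, c(2.5, 7.25)), 3 + 2 * c(2.5, 7.25),
               tolerance = 1e-12)
  expect_error(loess_fit(1:4, 1:4), "at least 5")
  expect_error(loess_fit(1:10, 1:10, span = 0.2), "span too small")
  expect_error(loess_fit(1:10, 1:10, span = 1.5), "span must be")
})

test_that("constant data produce a flat fit with zero-variance band", {
  fit <- loess_fit(1:8, rep(5, 8))
  pred <- predict(fit, c(1, 4.5, 8), se = TRUE)
  expect_equal(pred$fit, rep(5, 3), tolerance = 1e-12)
  expect_equal(pred$se, rep(0, 3), tolerance = 1e-12)
})

test_that("the fit tracks stats::loess closely on smooth data", {
  # stats::loess handles the tricube neighborhood slightly differently
  # (fractional neighbor weighting), so the two estimators are close but not
  # identical; on smooth, densely sampled data they should agree to ~1%.
  # Exact agreement with the stated tricube contract is tested separately
  # against an explicit single-point oracle.
  set.seed(3)
  x <- seq(1, 30)
  y <- 100 * (1 - exp(-x / 8)) + rnorm(30, sd = 0.5)
  ours <- loess_fit(x, y, span = 0.75)
  ref <- stats::loess(y ~ x, span = 0.75, degree = 1,
                      surface = "direct",
                      control = stats::loess.control(iterations = 1))
  grid <- seq(2, 29, by = 1.5)
  rel <- abs(predict(ours, grid) - unname(stats::predict(ref, grid))) /
    abs(unname(stats::predict(ref, grid)))
  expect_lt(max(rel), 0.01)
})

test_that("extrapolation clamps to the boundary and is flagged", {
  fit <- loess_fit(10:20, (10:20)^1.5)
  out <- predict(fit, c(5, 15, 30), se = TRUE)
  expect_equal(out$clamped, c(TRUE, FALSE, TRUE))
  expect_equal(out$fit[1], predict(fit, 10))
  expect_equal(out$fit[3], predict(fit, 20))
})

test_that("increments telescope to fit(max) - fit(0-clamp)", {
  set.seed(5)
  x <- seq(1e6, 5e7, length.out = 20)
  y <- 2000 * (1 - exp(-x / 1e7)) + rnorm(20, sd = 10)
  fit <- loess_fit(x, y)
  inc <- increments(fit, max_depth = 6e7, step = 5e5)
  expect_equal(sum(inc$increment), predict(fit, 6e7) - predict(fit, 0),
               tolerance = 1e-9)
  expect_equal(inc$depth_to - inc$depth_from, rep(5e5, nrow(inc)))
  # steps entirely below the training range are clamped and contribute 0
  expect_true(all(inc$increment[inc$depth_to <= 1e6] == 0))
  # saturation depth scans for the first sub-threshold increment
  sat <- saturation_depth(inc, threshold = 50)
  expect_true(is.na(sat) || sat %in% inc$depth_to)
  expect_true(is.na(saturation_depth(inc, threshold = -Inf)))
})

test_that("depth_series reads the requested metadata level", {
  mk <- function(id, total, mapped, assigned, cls) {
    toy_assembly(stats::setNames(list(list(exons = list(c(0, 300)))),
                                 paste0(id, "_t")),
                 attrs = data.frame(transcript_id = paste0(id, "_t"),
                                    coding_class = cls),
                 meta = sample_meta(sample_id = id, group_label = "g",
                                    total_reads = total,
                                    mapped_reads = mapped,
                                    assigned_reads = assigned))
  }
  asms <- list(mk("a", 100, 90, 80, "coding"), mk("b", 200, 150, 100,
                                                  "noncoding"))
  s_tot <- depth_series(asms)
  expect_equal(s_tot$depth, c(100, 200))
  expect_equal(depth_series(asms, "mapped")$depth, c(90, 150))
  expect_equal(depth_series(asms, "assigned")$depth, c(80, 100))
  expect_equal(s_tot$n_coding, c(1, 0))
  expect_equal(s_tot$n_noncoding, c(0, 1))
})

test_that("depth bins are half-open with boundary depths in the upper bin", {
  series <- data.frame(sample_id = letters[1:4], group_label = "g",
                       depth = c(5e6, 1e7, 1.5e7, 2e7 - 1),
                       n_all = c(10, 20, 30, 40),
                       n_coding = 0, n_noncoding = 0)
  b <- bin_by_depth(series, width = 1e7)
  expect_equal(b$bin, c(0, 1))
  expect_equal(b$n_samples, c(1, 3))     # 1e7 falls in bin 1, not bin 0
  expect_equal(b$depth_lo, c(0, 1e7))
  expect_equal(b$depth_hi, c(1e7, 2e7))
  expect_equal(b$median, c(10, 30))
  expect_equal(b$min, c(10, 20))
  expect_equal(b$max, c(10, 40))
})

test_that("coding:noncoding ratio propagates NA on zero denominators", {
  series <- data.frame(sample_id = c("a", "b"), group_label = "g",
                       depth = c(1, 2), n_all = c(3, 5),
                       n_coding = c(3, 4), n_noncoding = c(0, 1))
  r <- coding_noncoding_ratio(series)
  expect_true(is.na(r$ratio[1]))
  expect_equal(r$ratio[2], 4)
  asm <- toy_assembly(list(t = list(exons = list(c(0, 100)))),
                      attrs = data.frame(transcript_id = "t",
                                         coding_class = "coding"))
  expect_true(is.na(coding_noncoding_ratio(asm)))
})

test_that("observed_minus_predicted excludes under-replicated groups", {
  set.seed(9)
  depths <- seq(1e6, 2e7, length.out = 24)
  counts <- 3000 * (1 - exp(-depths / 5e6)) + rnorm(24, sd = 20)
  # interleave the groups across the depth ladder so every local
  # neighborhood mixes them (sizes: big 10, mid 9, small 5)
  groups <- rep_len(c("big", "mid", "big", "mid", "small"), 24)
  series <- data.frame(sample_id = sprintf("s%02d", 1:24),
                       group_label = groups, depth = depths,
                       n_all = counts, n_coding = 0, n_noncoding = 0)
  fit <- loess_fit(depths, counts)
  omp <- observed_minus_predicted(series, fit, min_replicates = 8)
  expect_setequal(unique(omp$group_label), c("big", "mid"))  # 7 < 8 excluded
  expect_equal(omp$deviation, omp$observed - omp$predicted)
  # a constant +delta shift in one group is recovered in its mean deviation
  shifted <- series
  shifted$n_all[shifted$group_label == "big"] <-
    shifted$n_all[shifted$group_label == "big"] + 500
  fit2 <- loess_fit(shifted$depth, shifted$n_all)
  omp2 <- observed_minus_predicted(shifted, fit2, min_replicates = 8)
  mean_big <- mean(omp2$deviation[omp2$group_label == "big"])
  mean_mid <- mean(omp2$deviation[omp2$group_label == "mid"])
  expect_gt(mean_big - mean_mid, 250)
})
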