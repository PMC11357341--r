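make_rec <- function(n = 1000, fr = 15, f = function(t) 10 + exp(-t / 30),
                     side = "left") {
  t <- (seq_len(n) - 1) / fr
  photometry_recording(time = t, F415 = f(t), F470 = 1.5 * f(t),
                       fiber_side = side, frame_rate = fr)
}

test_that("frame trimming drops frames, re-zeroes time and records the offset", {
  r <- make_rec(1000)
  tr <- trim_frames(r, 300)
  expect_length(tr$time, 700)
  expect_equal(tr$time[1], 0)
  expect_equal(tr$trim_offset, 20)
  expect_equal(tr$F415, r$F415[301:1000])
  expect_identical(trim_frames(r, 0), r)
  expect_error(trim_frames(make_rec(200), 300), "cannot trim")
})

test_that("noiseless biexponential parameters are recovered to high precision", {
  t <- (0:29999) / 15
  F <- 1 * exp(-t / 30) + 0.5 * exp(-t / 600) + 0.1
  fit <- fit_biexponential(t, F)
  co <- coef(fit)
  expect_true(fit$converged)
  expect_equal(unname(co["A1"]), 1, tolerance = 1e-3)
  expect_equal(unname(co["tau1"]), 30, tolerance = 1e-3)
  expect_equal(unname(co["A2"]), 0.5, tolerance = 1e-3)
  expect_equal(unname(co["tau2"]), 600, tolerance = 1e-3)
  expect_equal(unname(co["C"]), 0.1, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999999)
  expect_lte(co["tau1"], co["tau2"])
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, time = t[1:5]), fit$fitted[1:5])
})

test_that("a constant trace yields a degenerate but well-defined fit", {
  t <- (0:999) / 15
  fit <- fit_biexponential(t, rep(2.5, 1000))
  expect_equal(unname(coef(fit)["C"]) +
                 sum(abs(coef(fit)[c("A1", "A2")])), 2.5, tolerance = 1e-6)
  expect_equal(fit$fitted, rep(2.5, 1000), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1)   # zero total and residual variation
})

test_that("the bleach fit is deterministic and ordered tau1 <= tau2", {
  t <- (0:9999) / 15
  set.seed(1)
  F <- 2 * exp(-t / 20) + 1 * exp(-t / 300) + 5 + rnorm(length(t), 0, 0.02)
  f1 <- fit_biexponential(t, F)
  f2 <- fit_biexponential(t, F)
  expect_identical(coef(f1), coef(f2))
  expect_lte(coef(f1)["tau1"], coef(f1)["tau2"])
})

test_that("RANSAC recovers an exact line with every frame an inlier", {
  x <- 10 + exp(-(0:4999) / 500)
  y <- 2 * x + 1
  sc <- ransac_scale(x, y, seed = 5)
  expect_equal(sc$slope, 2, tolerance = 1e-12)
  expect_equal(sc$intercept, 1, tolerance = 1e-10)
  expect_true(all(sc$inlier_mask))
  expect_equal(sc$scaled_fit, sc$slope * x + sc$intercept)
})

test_that("RANSAC ignores displaced frames and flags them as outliers", {
  set.seed(2)
  x <- 10 + exp(-(0:4999) / 500)
  y <- 2 * x + 1
  hit <- sample(length(y), 500)          # 10% contamination
  y[hit] <- y[hit] + 5
  sc <- ransac_scale(x, y, seed = 5)
  expect_equal(sc$slope, 2, tolerance = 1e-6)
  expect_true(mean(sc$inlier_mask[hit]) < 0.01)
  expect_true(mean(sc$inlier_mask[-hit]) > 0.99)
})

test_that("RANSAC is deterministic given its seed and demands distinct x", {
  set.seed(3)
  x <- rnorm(500, 10)
  y <- 3 * x + rnorm(500, 0, 0.1)
  a <- ransac_scale(x, y, seed = 9)
  b <- ransac_scale(x, y, seed = 9)
  expect_identical(a$inlier_mask, b$inlier_mask)
  expect_identical(coef(a), coef(b))
  expect_error(ransac_scale(rep(1, 100), rnorm(100), seed = 1), "distinct")
})

test_that("the low-pass filter preserves DC and the passband and kills the stopband", {
  expect_equal(lowpass(rep(4.2, 500), 30), rep(4.2, 500), tolerance = 1e-8)
  t <- (0:2999) / 30
  mid <- 500:2500
  s1 <- sin(2 * pi * 1 * t)
  f1 <- lowpass(s1, 30)
  expect_equal(max(abs(f1[mid])), 1, tolerance = 0.01)
  s12 <- sin(2 * pi * 12 * t)
  f12 <- lowpass(s12, 30)
  expect_lt(max(abs(f12[mid])), 0.2)
  expect_warning(lowpass(s1, 10), "skipped")
  expect_error(lowpass(c(1, NA, 2), 30), "non-finite")
})

test_that("dF/F modes are the ratio and the ratio minus one", {
  f <- c(10, 11, 12, 10)
  ctrl <- c(10, 10, 10, 10)
  expect_equal(compute_dff(ctrl, ctrl, "ratio"), rep(1, 4))
  expect_equal(compute_dff(ctrl, ctrl, "subtract"), rep(0, 4))
  set.seed(4)
  a <- abs(rnorm(100)) + 1
  b <- abs(rnorm(100)) + 1
  expect_equal(compute_dff(a, b, "ratio") - compute_dff(a, b, "subtract"),
               rep(1, 100))
  expect_error(compute_dff(f, c(1, -1, 1, 1)), class = "photolick_qc_error")
})

test_that("session z-scoring is exact and affine-invariant", {
  set.seed(6)
  x <- rnorm(5000, 3, 0.5)
  z <- zscore_session(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_equal(zscore_session(2.5 * x + 7), z)
  # ratio and subtract dF/F z-score identically (they differ by a constant)
  ctrl <- abs(rnorm(5000)) + 5
  expect_equal(zscore_session(compute_dff(x + 5, ctrl, "ratio")),
               zscore_session(compute_dff(x + 5, ctrl, "subtract")))
  expect_error(zscore_session(rep(1, 100)), "zero-variance")
})

test_that("QC failure reasons are specific and machine-readable", {
  t <- (0:1999) / 15
  set.seed(7)
  F <- 2 * exp(-t / 20) + 1 * exp(-t / 200) + 5 + rnorm(2000, 0, 0.01)
  fit <- fit_biexponential(t, F)
  sc <- ransac_scale(fit$fitted, 1.5 * F, seed = 1)
  z <- rnorm(2000)
  expect_true(qc_recording(fit, sc, z, 15)$passed)

  bad_fit <- fit; bad_fit$r_squared <- 0.2
  expect_identical(qc_recording(bad_fit, sc, z, 15)$reason, "poor bleach fit")
  bad_sc <- sc; bad_sc$inlier_mask <- rep(c(TRUE, FALSE, FALSE), length.out = 2000)
  expect_identical(qc_recording(fit, bad_sc, z, 15)$reason,
                   "low inlier fraction")
  expect_identical(qc_recording(fit, sc, NULL, 15)$reason,
                   "nonpositive control fit")
  z2 <- z; z2[100:130] <- 20      # > 10 z for 2 s at 15 Hz
  expect_identical(qc_recording(fit, sc, z2, 15)$reason,
                   "excursion bound exceeded")
  z3 <- z; z3[100:105] <- 20      # brief excursion within the dwell limit
  expect_true(qc_recording(fit, sc, z3, 15)$passed)
})

test_that("process_recording applies the stages in the fixed order", {
  sim <- simulate_session(quick_config(seed = 13, duration = 900))
  tr <- process_recording(sim$left, seed = 77)
  # replay the chain by hand
  r <- trim_frames(sim$left, 300)
  fit <- fit_biexponential(r$time, r$F415)
  sc <- ransac_scale(fit$fitted, r$F470, seed = 77)
  f470 <- lowpass(r$F470, r$frame_rate)
  ctrl <- sc$slope * lowpass(r$F415, r$frame_rate) + sc$intercept
  dff <- compute_dff(f470, ctrl, "ratio")
  expect_identical(tr$zdff, zscore_session(dff))
  expect_identical(coef(tr$bleach_fit), coef(fit))
  expect_identical(tr$scale$inlier_mask, sc$inlier_mask)
  expect_true(tr$qc$passed)
})

test_that("a session with a nonpositive control fails QC with its reason", {
  sim <- simulate_session(quick_config(seed = 14, duration = 900))
  rec <- sim$left
  rec$F470 <- -rec$F470      # forces a negative scaled control
  tr <- process_recording(rec, seed = 1)
  expect_false(tr$qc$passed)
  expect_identical(tr$qc$reason, "nonpositive control fit")
  expect_null(tr$zdff)
})
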