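test_that("transient kernel has unit peak at the analytic argmax and is nonnegative", {
  k <- transient_kernel(0.1, 1.0, dt = 0.01)
  tt <- attr(k, "time")
  expect_equal(max(k), 1.0)
  t_star <- log(1.0 / 0.1) * (0.1 * 1.0) / (1.0 - 0.1)
  expect_equal(t_star, 0.2558428, tolerance = 1e-6)
  expect_equal(attr(k, "t_peak"), t_star)
  expect_lt(abs(tt[which.max(k)] - t_star), 0.01)
  expect_true(all(k >= 0))
  expect_equal(k[1], 0)
})

test_that("degenerate kernel time constants are rejected", {
  expect_error(transient_kernel(1.0, 1.0, dt = 0.01), "smaller")
  expect_error(transient_kernel(-0.1, 1.0, dt = 0.01), "positive")
  expect_error(transient_kernel(0.1, 0, dt = 0.01), "positive")
})

test_that("the generator is fully determined by its seed", {
  cf <- quick_config(seed = 1, n_leak = 1, n_chew = 1)
  a <- simulate_session(cf)
  b <- simulate_session(cf)
  expect_identical(a, b)
  # and a different seed changes the data
  d <- simulate_session(quick_config(seed = 2, n_leak = 1, n_chew = 1))
  expect_false(identical(a$left$F470, d$left$F470))
})

test_that("with no bouts, motion or noise, F470 is exactly the scaled bleach curve", {
  cf <- sim_config(session_duration = 600, channel_scale = 1.7,
                   noise_sigma = 0, motion = list(rate = 0, amplitude = 0, duration = 0.3),
                   bout_model = list(n_bouts = 0),
                   artifacts = list(n_leak = 0, n_chew = 0), seed = 3)
  sim <- simulate_session(cf)
  expect_equal(sim$left$F470, 1.7 * sim$left$F415)
  expect_length(sim$truth$drink_onsets, 0)
  expect_identical(nrow(sim$licks$records), 0L)
})

test_that("noise-free transients reach exactly amplitude times the kernel peak", {
  amap <- default_amplitude_map()
  amap$amplitude <- 3.0
  cf <- sim_config(session_duration = 900, noise_sigma = 0, amplitude_cv = 0,
                   motion = list(rate = 0, amplitude = 0, duration = 0.3),
                   amplitude_map = amap,
                   bout_model = list(n_bouts = 4, spacing_min = 60),
                   artifacts = list(n_leak = 0, n_chew = 0), seed = 4)
  sim <- simulate_session(cf)
  resid <- sim$left$F470 - cf$channel_scale * sim$left$F415
  for (o in sim$truth$drink_onsets) {
    win <- sim$left$time >= o & sim$left$time <= o + 10
    expect_equal(max(resid[win]), 3.0, tolerance = 1e-9)
  }
  expect_equal(sim$truth$amplitude_left, rep(3.0, 4))
})

test_that("frame count equals frame_rate times session duration", {
  sim <- simulate_session(quick_config(seed = 5, duration = 600))
  expect_length(sim$left$time, 15 * 600)
  expect_length(sim$right$F470, 15 * 600)
})

test_that("kernel support longer than the session is rejected", {
  cf <- quick_config(seed = 1, duration = 1200)
  cf$kernel$decay_tau <- 200
  expect_error(simulate_session(cf), "kernel support")
})

test_that("lick schedules respect bout structure and session bounds", {
  bm <- list(n_bouts = 6, events_per_bout = 10, bout_dispersion = 0.6,
             spacing_min = 6.5, lick_interval = 0.125, lick_duration = 0.05,
             duration_cv = 0.1)
  st <- make_lick_schedule(bm, 600, seed = 7)
  expect_equal(length(unique(st$bout)), 6)
  expect_true(all(st$onset + st$duration < 600))
  # inter-bout quiet gaps exceed spacing_min
  ends <- tapply(st$onset + st$duration, st$bout, max)
  starts <- tapply(st$onset, st$bout, min)
  expect_true(all(starts[-1] - ends[-6] > 6.5))
  # empty and infeasible cases
  bm0 <- bm; bm0$n_bouts <- 0
  expect_identical(nrow(make_lick_schedule(bm0, 600, seed = 1)), 0L)
  bmx <- bm; bmx$n_bouts <- 200
  expect_error(make_lick_schedule(bmx, 60, seed = 1), "infeasible")
})

test_that("binned drink count never exceeds bout count and matches it for spaced bouts", {
  set.seed(11)
  for (i in 1:200) {
    bm <- list(n_bouts = sample(1:8, 1), events_per_bout = sample(3:20, 1),
               bout_dispersion = runif(1, 0, 0.8), spacing_min = 6.5,
               lick_interval = 0.125, lick_duration = 0.05, duration_cv = 0.1)
    st <- make_lick_schedule(bm, 900, seed = i)
    rec <- bin_lick_stream(st, 900)
    dr <- bin_to_drinks(rec)
    expect_lte(nrow(dr), bm$n_bouts)
    expect_equal(nrow(dr), bm$n_bouts)  # spacing_min > 6 guarantees equality
  }
})

test_that("single bout of five licks in a 2-s span bins to one drink", {
  st <- data.frame(bout = 1L, onset = seq(10, 12, length.out = 5),
                   duration = 0.05)
  rec <- bin_lick_stream(st, 60)
  dr <- bin_to_drinks(rec)
  expect_identical(nrow(dr), 1L)
  expect_equal(dr$n_events, 5L)
  expect_equal(dr$start, 9)
})

test_that("leak injection multiplies drink duration while leaving events unchanged", {
  # breaks spaced so the 10x durations never overlap (broken time is wall time)
  st <- data.frame(bout = 1L, onset = seq(10, 20, by = 2.5),
                   duration = 0.2)
  inj <- inject_artifacts(st, list(n_leak = 1, leak_multiplier = 10,
                                   n_chew = 0, chew_multiplier = 10), seed = 1)
  expect_identical(inj$leak_bouts, 1L)
  expect_equal(sum(inj$stream$duration), 10 * sum(st$duration))
  expect_identical(nrow(inj$stream), nrow(st))
  d0 <- bin_to_drinks(bin_lick_stream(st, 120))
  d1 <- bin_to_drinks(bin_lick_stream(inj$stream, 120))
  expect_equal(d1$n_events, d0$n_events)
  expect_equal(d1$event_duration, 10 * d0$event_duration, tolerance = 1e-9)
})

test_that("chew injection inflates events at near-zero duration", {
  st <- data.frame(bout = 1L, onset = seq(10, 11, length.out = 5),
                   duration = 0.2)
  inj <- inject_artifacts(st, list(n_leak = 0, leak_multiplier = 10,
                                   n_chew = 1, chew_multiplier = 10), seed = 1)
  expect_identical(inj$chew_bouts, 1L)
  d1 <- bin_to_drinks(bin_lick_stream(inj$stream, 120))
  expect_equal(d1$n_events, 50L)
  expect_lt(d1$event_duration, 0.2)
})

test_that("artifact injection is identity when nothing is requested and errors when infeasible", {
  st <- data.frame(bout = rep(1:2, each = 3), onset = c(1, 1.2, 1.4, 30, 30.2, 30.4),
                   duration = 0.05)
  inj <- inject_artifacts(st, list(n_leak = 0, leak_multiplier = 10,
                                   n_chew = 0, chew_multiplier = 10), seed = 1)
  expect_identical(inj$stream, st)
  expect_error(
    inject_artifacts(st, list(n_leak = 2, leak_multiplier = 10,
                              n_chew = 1, chew_multiplier = 10), seed = 1),
    "artifact injections")
})

test_that("ground truth onsets match scheduled bouts and injected indices refer to drinks", {
  sim <- simulate_session(quick_config(seed = 9, n_bouts = 10,
                                       n_leak = 1, n_chew = 1))
  expect_length(sim$truth$drink_onsets, 10)
  dr <- bin_to_drinks(sim$licks)
  expect_true(all(c(sim$truth$leak_drinks, sim$truth$chew_drinks) %in% dr$drink))
  expect_true(all(sim$truth$drink_onsets >= 0 &
                    sim$truth$drink_onsets < sim$licks$duration))
})
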