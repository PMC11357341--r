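test_that("lick logs round-trip through the CSV dialect", {
  sim <- simulate_session(quick_config(seed = 2, n_leak = 1))
  path <- tempfile(fileext = ".csv")
  write_lick_log(sim$licks, path)
  back <- read_lick_log(path)
  expect_equal(back$records, sim$licks$records, tolerance = 1e-12)
  expect_identical(back$animal_id, sim$licks$animal_id)
  expect_equal(back$bottle_pre, sim$licks$bottle_pre)
  expect_equal(back$duration, sim$licks$duration)
})

test_that("malformed lick logs are rejected with the offending row", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# animal_id: a1", "bin_start_s,n_events,event_duration_s",
               "0,2,0.8", "3,1,3.5"), path)
  expect_error(read_lick_log(path), "line 4")
  writeLines(c("bin_start_s,n_events", "0,2"), path)
  expect_error(read_lick_log(path), "missing columns")
  writeLines(c("bin_start_s,n_events,event_duration_s",
               "6,2,0.8", "3,1,0.5"), path)
  expect_error(read_lick_log(path), "increasing")
  expect_error(read_lick_log(tempfile()), "no such file")
})

test_that("a session with zero records is valid", {
  s <- lick_session("a", "male", "water", 1, 1, 7200,
                    data.frame(bin_start = numeric(0), n_events = integer(0),
                               event_duration = numeric(0)),
                    100, 100, 25)
  expect_identical(nrow(bin_to_drinks(s)), 0L)
  m <- microstructure(s)
  expect_true(is.na(m$latency_s))
  expect_identical(m$n_drinks, 0L)
  expect_equal(m$intake_gkg, 0)
})

test_that("session invariants are enforced", {
  rec <- data.frame(bin_start = c(0, 4), n_events = 1L, event_duration = 0.5)
  expect_error(lick_session("a", "male", "water", 1, 1, 60, rec, 100, 99, 25),
               "multiple of 3")
  rec2 <- data.frame(bin_start = c(0, 3), n_events = 1L, event_duration = 3.2)
  expect_error(lick_session("a", "male", "water", 1, 1, 60, rec2, 100, 99, 25),
               "outside")
  rec3 <- data.frame(bin_start = 0, n_events = 1L, event_duration = 0.5)
  expect_error(lick_session("a", "male", "water", 1, 1, 60, rec3, 99, 100, 25),
               "bottle_post")
})

test_that("adjacent occupied windows merge into one drink, separated windows do not", {
  rec <- data.frame(bin_start = c(0, 3), n_events = c(2L, 1L),
                    event_duration = c(0.8, 0.2))
  d <- bin_to_drinks(rec)
  expect_identical(nrow(d), 1L)
  expect_equal(c(d$start, d$end, d$length), c(0, 6, 6))
  expect_equal(d$n_events, 3L)
  expect_equal(d$event_duration, 1.0)

  rec2 <- data.frame(bin_start = c(0, 9), n_events = c(2L, 1L),
                     event_duration = c(0.8, 0.2))
  d2 <- bin_to_drinks(rec2)
  expect_identical(nrow(d2), 2L)
  expect_equal(d2$start, c(0, 9))
})

test_that("drink merging matches a brute-force scan and leaves no mergeable gaps", {
  set.seed(21)
  for (i in 1:300) {
    rec <- random_records(n_bins = sample(10:60, 1), p_occ = runif(1, 0.1, 0.9))
    d <- bin_to_drinks(rec)
    o <- oracle_merge(rec)
    expect_equal(d$start, o$start)
    expect_equal(d$end, o$end)
    expect_equal(d$n_events, o$n_events)
    expect_equal(d$event_duration, o$event_duration)
    # merged drinks are maximal: gaps of at least one empty window remain
    if (nrow(d) > 1L) expect_true(all(d$start[-1] - d$end[-nrow(d)] >= 3))
    # event conservation against the raw records
    expect_equal(sum(d$n_events), sum(rec$n_events))
  }
})

test_that("cleaning keeps colinear drinks and removes a single displaced one", {
  dur <- seq(0.2, 2.1, by = 0.1)
  drinks <- data.frame(drink = seq_along(dur), start = seq_along(dur) * 9,
                       end = seq_along(dur) * 9 + 3,
                       n_events = as.integer(round(2 + 20 * dur)),
                       event_duration = dur,
                       length = 3)
  cl <- clean_events(drinks)
  expect_identical(nrow(cl$removed), 0L)
  expect_equal(cl$model$slope, 20, tolerance = 1e-6)
  # displace one drink by +10 events
  drinks2 <- drinks
  drinks2$n_events[7] <- drinks2$n_events[7] + 10L
  cl2 <- clean_events(drinks2)
  expect_identical(cl2$removed$drink, 7L)
  expect_identical(nrow(cl2$kept), nrow(drinks) - 1L)
  # independent OLS on the clean subset agrees about the residual sign
  ols <- lm(n_events ~ event_duration, data = drinks2[-7, ])
  pred <- predict(ols, newdata = drinks2[7, , drop = FALSE])
  expect_gt(drinks2$n_events[7] - pred, 3)
})

test_that("cleaning passes through tiny or degenerate drink sets with a warning", {
  two <- data.frame(drink = 1:2, start = c(0, 9), end = c(3, 12),
                    n_events = c(5L, 7L), event_duration = c(0.3, 0.4),
                    length = 3)
  expect_warning(cl <- clean_events(two), "fewer than 3")
  expect_identical(cl$kept, two)
  same_dur <- data.frame(drink = 1:5, start = (0:4) * 9, end = (0:4) * 9 + 3,
                         n_events = as.integer(c(4, 5, 6, 5, 4)),
                         event_duration = 0.5, length = 3)
  expect_warning(cl2 <- clean_events(same_dur), "degenerate")
  expect_identical(nrow(cl2$removed), 0L)
})

test_that("cleaning conserves events between kept and removed sets", {
  set.seed(5)
  for (i in 1:20) {
    sim <- simulate_session(quick_config(seed = i, n_bouts = 15,
                                         n_leak = 1, n_chew = 1))
    d <- bin_to_drinks(sim$licks)
    cl <- clean_events(d)
    expect_equal(sum(cl$kept$n_events) + sum(cl$removed$n_events),
                 sum(d$n_events))
  }
})

test_that("latency, inter-drink interval and front-loading follow their definitions", {
  rec <- data.frame(bin_start = c(102, 402), n_events = c(3L, 5L),
                    event_duration = c(0.4, 0.6))
  s <- lick_session("a", "male", "water", 1, 1, 7200, rec, 100, 99, 25)
  m <- microstructure(s, clean = FALSE)
  expect_equal(m$latency_s, 102)
  expect_equal(m$mean_idi_s, 300)
  expect_equal(m$frontload_events, 8L)  # both before 1800 s

  one <- lick_session("a", "male", "water", 1, 1, 7200,
                      rec[1, , drop = FALSE], 100, 99, 25)
  expect_true(is.na(microstructure(one, clean = FALSE)$mean_idi_s))
})

test_that("front-loading equals a brute-force count of pre-1800-s events", {
  set.seed(31)
  for (i in 1:200) {
    s <- random_session(n_bins = 800, p_occ = 0.2, duration = 2400)
    m <- microstructure(s, clean = FALSE)
    r <- s$records
    expect_identical(m$frontload_events, sum(r$n_events[r$bin_start < 1800]))
    expect_identical(m$total_events, sum(r$n_events))
  }
})

test_that("gram-per-kilogram intakes follow the density arithmetic", {
  expect_equal(compute_intake(100, 99, 25, "water"), 40)
  expect_equal(compute_intake(100, 100 - 0.9687, 25, "alcohol"),
               0.20 * 0.78945 / 0.025, tolerance = 1e-10)
  expect_equal(compute_intake(100, 100 - 0.9687, 25, "alcohol"),
               6.3156, tolerance = 1e-4)
  expect_equal(compute_intake(80, 80, 25, "water"), 0)
  expect_error(compute_intake(99, 100, 25, "water"), "negative consumption")
})

test_that("inter-session intake equals the water intake arithmetic", {
  expect_equal(intersession_intake(150, 147.5, 25), 100)
  expect_equal(intersession_intake(150, 150, 25), 0)
  set.seed(41)
  for (i in 1:50) {
    pre <- runif(1, 100, 200)
    post <- pre - runif(1, 0, 5)
    bw <- runif(1, 18, 32)
    expect_identical(intersession_intake(pre, post, bw),
                     compute_intake(pre, post, bw, "water"))
  }
})
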