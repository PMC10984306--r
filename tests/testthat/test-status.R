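# Status classification, duration bins, sleep scoring, phase segmentation.

mk_events <- function(durations, gap = 30) {
  if (length(durations) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0)))
  }
  starts <- cumsum(c(10, head(durations, -1) + gap))
  ev <- data.frame(start_s = starts, end_s = starts + durations)
  ev$duration_s <- durations
  ev
}

test_that("only discharges of a minute or more become status events", {
  ev <- mk_events(c(59.9, 61, 1560))
  st <- classify_status(ev)
  expect_equal(nrow(st), 2)
  expect_equal(as.character(st$bin), c("B1", "B3"))
  expect_equal(st$duration_s, c(61, 1560))
})

test_that("duration bins are left-closed at their boundaries", {
  st <- classify_status(mk_events(c(60, 119.999, 120, 299.999, 300, 2000)))
  expect_equal(as.character(st$bin), c("B1", "B1", "B2", "B2", "B3", "B3"))
})

test_that("bin counting sums to the number of status events", {
  expect_equal(bin_durations(classify_status(mk_events(numeric(0)))),
               c(B1 = 0L, B2 = 0L, B3 = 0L))
  st <- classify_status(mk_events(c(70, 130, 400)))
  expect_equal(bin_durations(st), c(B1 = 1L, B2 = 1L, B3 = 1L))
  expect_equal(sum(bin_durations(st)), nrow(st))
})

test_that("wake background contains no sleep intervals", {
  set.seed(23)
  rec <- eeg_record(make_background(400, 200, 20),
                    make_background(400, 200, 20), 200)
  sl <- detect_sleep(rec)
  expect_equal(nrow(sl), 0)
})

test_that("an injected sleep block is recovered with < 5 s boundary error", {
  fs <- 200
  set.seed(24)
  wake1 <- make_background(200, fs, 20)
  sleep <- make_sleep_segment(180, fs, spindle_density_per_min = 2,
                              sigma_uv = 25)
  wake2 <- make_background(150, fs, 20)
  x <- c(wake1, 0.3 * make_background(180, fs, 20) + sleep, wake2)
  rec <- eeg_record(x, x + make_background(530, fs, 7), fs)
  sl <- detect_sleep(rec)
  expect_equal(nrow(sl), 1)
  expect_lt(abs(sl$start_s - 200), 5)
  expect_lt(abs(sl$end_s - 380), 5)
})

test_that("sleep intervals never overlap detected discharges", {
  sess <- generate_dex_session(session_config(seed = 19))
  rec_f <- bandpass(sess$record)
  ev <- detect_swds(rec_f, dex_detection_config(), filter = FALSE)
  sl <- detect_sleep(rec_f, ev)
  expect_gte(nrow(sl), 1)
  for (i in seq_len(nrow(sl))) {
    ov <- pmax(0, pmin(sl$end_s[i], ev$end_s) - pmax(sl$start_s[i],
                                                     ev$start_s))
    expect_true(all(ov <= 0))
  }
})

test_that("segmentation derives latencies from event and sleep timing", {
  # initial status starting 164 s after injection -> onset 164/60 = 2.733
  inj <- 2400
  st <- classify_status(data.frame(
    start_s = c(inj + 164, inj + 3000, inj + 3400),
    end_s = c(inj + 164 + 130, inj + 3100, inj + 3700),
    duration_s = c(130, 100, 300)))
  sl <- data.frame(start_s = inj + 6.8 * 60, end_s = inj + 6.8 * 60 + 1800)
  ph <- segment_session(st, sl, inj)
  expect_equal(ph$initial_status_onset_min, 164 / 60, tolerance = 1e-8)
  expect_equal(ph$sleep_latency_min, 6.8)
  expect_equal(ph$sleep_duration_min, 30)
  expect_equal(nrow(ph$initial_status), 1)
  expect_equal(nrow(ph$second_period), 2)
  expect_equal(ph$second_period_mean_duration_s, 200)
  # partition: every status event lands in exactly one phase
  expect_equal(nrow(ph$initial_status) + nrow(ph$second_period), nrow(st))
})

test_that("a session without post-injection status yields empty phases", {
  st <- classify_status(data.frame(start_s = numeric(0),
                                   end_s = numeric(0),
                                   duration_s = numeric(0)))
  ph <- segment_session(st, data.frame(start_s = numeric(0),
                                       end_s = numeric(0)), 2400)
  expect_false(ph$has_post_injection_status)
  expect_equal(nrow(ph$initial_status), 0)
  expect_equal(nrow(ph$second_period), 0)
  expect_true(is.na(ph$initial_status_onset_min))
  expect_true(is.na(ph$sleep_latency_min))
})
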