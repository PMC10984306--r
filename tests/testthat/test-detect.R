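# Band-pass, background amplitude, SWD detection, per-bin metrics.

test_that("bandpass passes in-band tones and stops out-of-band tones", {
  fs <- 200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  in_tone <- sin(2 * pi * 10 * t)
  out_tone <- sin(2 * pi * 50 * t)
  y_in <- bandpass(in_tone, 1, 40, sampling_rate = fs)
  y_out <- bandpass(out_tone, 1, 40, sampling_rate = fs)
  # FFT amplitude ratio oracle, central samples to avoid edge transients
  mid <- 400:1600
  gain_in <- max(periodogram_amplitude(y_in[mid], fs, 10)) /
    max(periodogram_amplitude(in_tone[mid], fs, 10))
  atten_out <- band_power(y_out[mid], fs, 45, 55) /
    band_power(out_tone[mid], fs, 45, 55)
  expect_lt(abs(20 * log10(gain_in)), 1)        # within +/- 1 dB
  expect_lt(10 * log10(atten_out), -20)         # >= 20 dB attenuation
  expect_error(bandpass(in_tone, 1, 150, sampling_rate = fs), "Nyquist")
  expect_error(bandpass(in_tone, 40, 1, sampling_rate = fs), "low")
})

test_that("background amplitude is morphology-consistent and robust", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  sine <- 30 * sin(2 * pi * 10 * t)
  est_sine <- estimate_background_amplitude(sine, fs)
  expect_lt(abs(est_sine - 30) / 30, 0.1)
  # sparse 3x transients move the estimate by < 15%
  clean <- make_background(120, fs, 20, seed = 8)
  dirty <- clean
  set.seed(9)
  for (s in sample(seq_len(length(clean) - fs), 20)) {
    dirty[s:(s + fs - 1)] <- 3 * dirty[s:(s + fs - 1)]
  }
  est_clean <- estimate_background_amplitude(clean, fs)
  est_dirty <- estimate_background_amplitude(dirty, fs)
  expect_lt(abs(est_dirty - est_clean) / est_clean, 0.15)
  expect_error(estimate_background_amplitude(rnorm(100), fs),
               "insufficient")
})

test_that("pure background yields no detections", {
  set.seed(12)
  rec <- eeg_record(make_background(600, 200, 20),
                    make_background(600, 200, 20), 200)
  ev <- detect_swds(rec, detection_config())
  expect_equal(nrow(ev), 0)
})

test_that("sub-second trains are rejected, near gaps are merged", {
  # 0.8-s train at 3x background: below the 1-s duration criterion
  fs <- 200; sigma <- 20
  set.seed(13)
  bg <- make_background(120, fs, sigma)
  amp3 <- 3 * qnorm(0.975) * sigma
  x <- bg
  tr <- make_swd_train(0.8, 7, amp3, fs)
  x[(60 * fs + 1):(60 * fs + length(tr))] <-
    x[(60 * fs + 1):(60 * fs + length(tr))] + tr
  ev <- detect_swds(eeg_record(x, x, fs), detection_config())
  expect_equal(nrow(ev), 0)

  # two 3-s trains separated by 0.5 s: merged into one ~6.5-s event
  x2 <- bg
  for (t0 in c(60, 63.5)) {
    tr <- make_swd_train(3, 7, amp3, fs)
    i0 <- round(t0 * fs) + 1
    x2[i0:(i0 + length(tr) - 1)] <- x2[i0:(i0 + length(tr) - 1)] + tr
  }
  ev2 <- detect_swds(eeg_record(x2, x2, fs), detection_config())
  expect_equal(nrow(ev2), 1)
  expect_lt(abs(ev2$duration_s - 6.5), 0.3)
})

test_that("detection recovers injected trains exactly across seeded records", {
  # 20 trains at known times in each of several seeded records; ground
  # truth is the generator's injection schedule
  for (seed in 1:6) {
    set.seed(seed)
    starts <- cumsum(runif(20, 15, 20))
    durs <- runif(20, 5, 10)  # inter-train gaps stay >= 5 s
    total <- max(starts + durs) + 10
    rec <- make_train_record(total, starts, durs, seed = 100 + seed)
    ev <- detect_swds(rec, detection_config())
    ms <- match_stats(data.frame(start_s = starts, end_s = starts + durs), ev)
    expect_equal(unname(ms["recall"]), 1)
    expect_equal(unname(ms["precision"]), 1)
  }
})

test_that("detector output is invariant to overall rescaling", {
  set.seed(3)
  starts <- cumsum(runif(5, 10, 20)); durs <- runif(5, 2, 5)
  rec <- make_train_record(max(starts + durs) + 10, starts, durs, seed = 44)
  rec2 <- rec
  rec2$left_uv <- rec2$left_uv * 13.7
  rec2$right_uv <- rec2$right_uv * 13.7
  ev1 <- detect_swds(rec, detection_config())
  ev2 <- detect_swds(rec2, detection_config())
  expect_equal(ev1$start_s, ev2$start_s)
  expect_equal(ev1$end_s, ev2$end_s)
})

test_that("emitted events honour duration and separation constraints", {
  sess <- generate_dex_session(session_config(seed = 17))
  ev <- detect_swds(bandpass(sess$record), dex_detection_config(),
                    filter = FALSE)
  cfg <- dex_detection_config()
  expect_true(all(ev$duration_s >= cfg$min_event_duration))
  if (nrow(ev) > 1) {
    gaps <- ev$start_s[-1] - ev$end_s[-nrow(ev)]
    expect_true(all(gaps >= cfg$merge_gap))
  }
  expect_true(all(vapply(ev$cycle_peak_voltages, length, 1L) > 0))
})

test_that("per-bin metrics apportion durations and count by start bin", {
  empty <- swd_metrics(data.frame(start_s = numeric(0),
                                  end_s = numeric(0)), 3600)
  expect_true(all(empty$total_s == 0 & empty$count == 0 & empty$mean_s == 0))
  expect_true(all(empty$empty))

  ev <- data.frame(start_s = c(10, 100), end_s = c(15, 120))
  m <- swd_metrics(ev, 1200, bin_width_s = 1200)
  expect_equal(m$total_s, 25)
  expect_equal(m$count, 2)
  expect_equal(m$mean_s, 12.5)

  # conservation: binned totals sum to the total event duration, and an
  # event crossing a boundary is apportioned by overlap but counted once
  ev2 <- data.frame(start_s = c(100, 1150, 2500), end_s = c(160, 1300, 2560))
  m2 <- swd_metrics(ev2, 3600, bin_width_s = 1200)
  expect_equal(sum(m2$total_s), sum(ev2$end_s - ev2$start_s))
  expect_equal(sum(m2$count), nrow(ev2))
  expect_equal(m2$count, c(2L, 0L, 1L))
  expect_equal(m2$total_s[1], 60 + 50)
})
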