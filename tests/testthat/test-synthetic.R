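# Synthetic EEG generator: background, spike-wave trains, sleep, sessions.

test_that("background noise has the requested RMS, band limits, and 1/f tilt", {
  expect_identical(make_background(0, 200, 20, seed = 1), numeric(0))
  x <- make_background(60, 200, 20, seed = 1)
  expect_length(x, 60 * 200)
  expect_lt(abs(mean(x)), 1e-8)
  expect_lt(abs(sqrt(mean(x^2)) - 20) / 20, 0.1)
  # log-power vs log-frequency slope over 2-40 Hz must be negative
  P <- Mod(fft(x - mean(x)))^2
  f <- (0:(length(x) - 1)) * 200 / length(x)
  sel <- f >= 2 & f <= 40
  slope <- coef(lm(log(P[sel]) ~ log(f[sel])))[2]
  expect_lt(slope, 0)
  expect_error(make_background(-1, 200, 20), "duration")
  expect_error(make_background(10, 200, -5), "sigma")
})

test_that("spike-wave trains put the fundamental and harmonics on the grid", {
  expect_identical(make_swd_train(0, 7, 100, 200, seed = 1), numeric(0))
  x <- make_swd_train(10, 7, 100, 200, seed = 1)
  A <- periodogram_amplitude(x, 200, 1:40)
  expect_equal(which.max(A), 7)
  # local maxima at the 2nd and 3rd harmonic
  expect_gt(A[14], A[13]); expect_gt(A[14], A[15])
  expect_gt(A[21], A[20]); expect_gt(A[21], A[22])
  expect_error(make_swd_train(5, 0.5, 100, 200), "fundamental")
  expect_error(make_swd_train(5, 12, 100, 200), "fundamental")
  expect_error(make_swd_train(5, 10, 100, 50), "Nyquist")
})

test_that("per-cycle peaks track the requested amplitude", {
  amp <- 100
  x <- make_swd_train(20, 7, amp, 200, seed = 2)
  cyc <- floor((seq_along(x) - 1) * 7 / 200)
  peaks <- vapply(split(x, cyc), max, numeric(1))
  expect_gt(mean(peaks) / amp, 0.9)
  expect_lt(mean(peaks) / amp, 1.1)
})

test_that("a train at twice the background amplitude satisfies the detector rule", {
  fs <- 200; sigma <- 20
  set.seed(5)
  bg <- make_background(120, fs, sigma)
  amp <- 2.2 * qnorm(0.975) * sigma  # just above the 2x threshold
  tr <- make_swd_train(10, 7, amp, fs)
  x <- bg
  i0 <- 50 * fs + 1
  x[i0:(i0 + length(tr) - 1)] <- x[i0:(i0 + length(tr) - 1)] + tr
  rec <- eeg_record(x, x, fs)
  ev <- detect_swds(rec, detection_config())
  expect_equal(nrow(ev), 1)
  expect_true(interval_matched(50, 60, ev$start_s, ev$end_s))
})

test_that("sleep segments are delta-dominant with optional spindles", {
  expect_identical(make_sleep_segment(0, 200, seed = 1), numeric(0))
  x <- make_sleep_segment(120, 200, spindle_density_per_min = 2, seed = 3)
  p_delta <- band_power(x, 200, 1, 4)
  for (lo in seq(5, 36, by = 4)) {
    expect_gt(p_delta, band_power(x, 200, lo, lo + 3))
  }
  # density 0: no 10-16 Hz power excess over a matched no-spindle draw
  a <- make_sleep_segment(120, 200, spindle_density_per_min = 0, seed = 4)
  b <- make_sleep_segment(120, 200, spindle_density_per_min = 8, seed = 4)
  expect_lt(band_power(a, 200, 10, 16), band_power(b, 200, 10, 16))
  expect_error(make_sleep_segment(10, 200, spindle_density_per_min = -1),
               "density")
})

test_that("default sessions realise the expected timeline structure", {
  sess <- generate_dex_session(session_config(seed = 11))
  tr <- sess$truth
  kinds <- tr$events$kind
  expect_equal(sum(kinds == "status_initial"), 1)
  expect_equal(nrow(tr$sleep), 1)
  expect_gte(sum(kinds == "status_second"), 1)
  durs <- tr$events$end_s - tr$events$start_s
  # every status >= 60 s; every baseline discharge in [1, 60)
  expect_true(all(durs[kinds != "swd"] >= 60))
  expect_true(all(durs[kinds == "swd"] >= 1 & durs[kinds == "swd"] < 60))
  # sorted, non-overlapping, half-open intervals
  expect_false(is.unsorted(tr$events$start_s))
  expect_true(all(diff(as.vector(rbind(tr$events$start_s,
                                       tr$events$end_s))) >= 0))
  # sleep strictly between initial status and second period
  init_end <- max(tr$events$end_s[kinds == "status_initial"])
  sec_start <- min(tr$events$start_s[kinds == "status_second"])
  expect_gt(tr$sleep$start_s, init_end)
  expect_gt(sec_start, tr$sleep$end_s)
})

test_that("sessions are bit-identical under a fixed seed", {
  a <- generate_dex_session(session_config(seed = 21))
  b <- generate_dex_session(session_config(seed = 21))
  expect_identical(a$record$left_uv, b$record$left_uv)
  expect_identical(a$record$right_uv, b$record$right_uv)
  expect_identical(a$truth, b$truth)
})

test_that("zeroed second-period weights produce no second-period events", {
  cfg <- session_config(seed = 5, second_period_bin_weights = c(0, 0, 0))
  sess <- generate_dex_session(cfg)
  expect_equal(sum(sess$truth$events$kind == "status_second"), 0)
})

test_that("amplitude contract holds for injected discharges", {
  cfg <- session_config(seed = 31)
  sess <- generate_dex_session(cfg)
  tr <- sess$truth
  fs <- cfg$sampling_rate
  x <- sess$record$left_uv
  ev <- tr$events[tr$events$kind == "status_initial", ][1, ]
  seg <- x[(round(ev$start_s * fs) + 1):round(ev$end_s * fs)]
  cyc <- floor((seq_along(seg) - 1) * ev$fundamental_hz / fs)
  peaks <- vapply(split(seg, cyc), max, numeric(1))
  bg_amp <- qnorm(0.975) * cfg$sigma_uv
  expect_gte(mean(peaks) / bg_amp, cfg$amplitude_ratio * 0.9)
})

test_that("ground-truth statistics across seeded sessions match the config", {
  # parameter-recovery closure of the generator itself (no detector): the
  # annotation layer is sampled for 150 seeds and its statistics compared
  # with the configured means
  cfg0 <- session_config()
  stats <- t(vapply(1:150, function(s) {
    tr <- sample_session_timeline(session_config(seed = 4000 + s))
    ev <- tr$events
    init <- ev[ev$kind == "status_initial", ]
    c(onset = (init$start_s[1] - tr$injection_time_s) / 60,
      latency = (tr$sleep$start_s - tr$injection_time_s) / 60,
      sleep_dur = (tr$sleep$end_s - tr$sleep$start_s) / 60,
      init_dur = init$end_s[1] - init$start_s[1])
  }, numeric(4)))
  targets <- c(cfg0$initial_status_onset_mean_min,
               cfg0$sleep_latency_mean_min,
               cfg0$sleep_duration_mean_min,
               cfg0$initial_status_duration_mean_s)
  for (j in seq_len(ncol(stats))) {
    mu <- mean(stats[, j])
    se <- sd(stats[, j]) / sqrt(nrow(stats))
    expect_lt(abs(mu - targets[j]), 3 * se)
  }
})
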