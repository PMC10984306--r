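# Multitaper PSD, coherence, spectral peaks, group comparison, variance test.

fs <- 200
tone <- function(f, amp = 1, dur = 5) {
  amp * sin(2 * pi * f * seq(0, dur - 1 / fs, by = 1 / fs))
}

test_that("epoch selection follows the first/mid/last definitions", {
  rec <- eeg_record(seq_len(40000), seq_len(40000), fs)
  ev <- data.frame(start_s = 100, end_s = 130)
  expect_equal(select_epochs(ev, rec, "first5")$start_s, 100)
  expect_equal(select_epochs(ev, rec, "mid5")$start_s, 112.5)
  expect_equal(select_epochs(ev, rec, "last5")$start_s, 125)
  expect_length(select_epochs(ev, rec, "first5")$left, 5 * fs)
  short <- data.frame(start_s = 100, end_s = 115)
  expect_error(select_epochs(short, rec, "first5"), "minimum is 20")
  expect_equal(select_epochs(short, rec, "mid5", min_event_s = 10)$start_s,
               105)
})

test_that("multitaper PSD peaks at a pure tone and covers the 1-40 Hz grid", {
  psd <- multitaper_psd(tone(10), fs)
  expect_identical(psd$freqs_hz, 1:40)
  expect_length(psd$power, 40)
  expect_equal(psd$freqs_hz[which.max(psd$power)], 10)
  expect_true(all(psd$power >= 0))
  expect_error(multitaper_psd(tone(10, dur = 4), fs), "epoch")
})

test_that("PSD scales linearly with the signal (amplitude convention)", {
  x <- tone(7) + 0.3 * tone(14)
  a <- multitaper_psd(x, fs)$power
  b <- multitaper_psd(3.7 * x, fs)$power
  expect_equal(b, 3.7 * a, tolerance = 1e-10)
})

test_that("white-noise spectra are flat and taper averaging reduces variance", {
  set.seed(31)
  rel_dev <- replicate(20, {
    p <- multitaper_psd(rnorm(1000), fs)$power^2
    sd(p) / mean(p)
  })
  # chi^2_{2K} relative SD is 1/sqrt(K) = 1/3 for K = 9; allow 3x
  expect_lt(mean(rel_dev), 1)
  # variance across realisations, per frequency: multitaper < single taper
  many_mt <- replicate(100, multitaper_psd(rnorm(1000), fs)$power^2)
  single <- replicate(100, {
    X <- fft(rnorm(1000))
    Mod(X[1 + 5 * (1:40)])^2
  })
  expect_lt(mean(apply(many_mt, 1, var)) / mean(many_mt)^2,
            mean(apply(single, 1, var)) / mean(single)^2)
})

test_that("coherence is bounded, 1 for identical channels, low when independent", {
  x <- tone(7) + rnorm(1000)
  c_same <- mt_coherence(x, x, fs)
  expect_true(all(c_same$coherence >= 0 & c_same$coherence <= 1))
  expect_true(all(abs(c_same$coherence - 1) < 1e-10))
  # Monte-Carlo under independence: mean coherence across the grid < 0.5
  set.seed(32)
  mean_c <- replicate(10, {
    mean(mt_coherence(rnorm(1000), rnorm(1000), fs)$coherence)
  })
  expect_true(all(mean_c < 0.5))
  expect_error(mt_coherence(rnorm(1000), rnorm(999), fs), "length")
})

test_that("coherence is highest at the shared discharge rhythm", {
  set.seed(33)
  common <- make_swd_train(5, 7, 100, fs)
  l <- common + make_background(5, fs, 15)
  r <- common + make_background(5, fs, 15)
  coh <- mt_coherence(l, r, fs)$coherence
  non_harmonic <- setdiff(1:40, c(6, 7, 8, 14, 21, 28, 35))
  expect_gt(coh[7], mean(coh[non_harmonic]))
})

test_that("spectral peaks are ordered local maxima; harmonics are found", {
  mono <- list(freqs_hz = 1:40, power = 40:1 / 40)
  expect_identical(find_spectral_peaks(mono), numeric(0))
  psd7 <- multitaper_psd(make_swd_train(5, 7, 100, fs, seed = 2), fs)
  pk7 <- find_spectral_peaks(psd7)
  expect_true(all(c(7, 14, 21) %in% pk7))
  psd5 <- multitaper_psd(make_swd_train(5, 5, 100, fs, seed = 2), fs)
  pk5 <- find_spectral_peaks(psd5)
  expect_equal(pk5[1], 5)
})

test_that("group comparison finds band-limited power differences and is FDR-controlled", {
  set.seed(34)
  n <- 8
  base_psd <- function(boost) {
    x <- make_background(5, fs, 20)
    if (boost) {
      x <- x + fft_filtered_delta()
    }
    multitaper_psd(x, fs)$power
  }
  fft_filtered_delta <- function() {
    d <- rnorm(1000)
    d <- bandpass(d, 1, 4, sampling_rate = fs)
    d / sd(d) * 40  # 4x power in the delta band
  }
  g_a <- t(replicate(n, base_psd(TRUE)))
  g_b <- t(replicate(n, base_psd(FALSE)))
  res <- compare_psd_groups(g_a, g_b, freqs = 1:40, q = 0.01)
  sig <- res$freq_hz[res$significant]
  expect_gt(length(sig), 0)
  expect_true(all(sig <= 8))  # contained in a band including 1-4 Hz
  # identical groups: nothing significant
  res0 <- compare_psd_groups(g_b, g_b, freqs = 1:40)
  expect_equal(sum(res0$significant), 0)
  expect_error(compare_psd_groups(g_a[1, , drop = FALSE], g_b),
               "insufficient")
})

test_that("lowering the FDR level never adds significant frequencies", {
  set.seed(35)
  g_a <- matrix(rnorm(8 * 40, mean = rep(c(2, 0), c(10, 30))), 8, 40,
                byrow = TRUE)
  g_b <- matrix(rnorm(8 * 40), 8, 40)
  qs <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  sets <- lapply(qs, function(q) {
    r <- compare_psd_groups(g_a, g_b, freqs = 1:40, q = q)
    r$freq_hz[r$significant]
  })
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("variance test has df = 2 for three groups and detects 4x variance", {
  set.seed(36)
  g <- lapply(1:3, function(i) rnorm(50, sd = 10))
  res <- peak_voltage_variance_test(g)
  expect_equal(res$df, 2)
  g2 <- list(rnorm(50, sd = 10), rnorm(50, sd = 10), rnorm(50, sd = 20))
  power <- mean(replicate(200, {
    g2 <- list(rnorm(50, sd = 10), rnorm(50, sd = 10), rnorm(50, sd = 20))
    peak_voltage_variance_test(g2)$p_value < 0.01
  }))
  expect_gte(power, 0.9)
  expect_error(peak_voltage_variance_test(g[1:2]), "three groups")
  expect_error(peak_voltage_variance_test(list(rnorm(3), rnorm(50),
                                               rnorm(50))), "at least 5")
})

test_that("FDR correction across animals flags adjusted p-values", {
  p <- c(0.001, 0.002, 0.03, 0.8)
  res <- fdr_correct(p, q = 0.05)
  expect_equal(res$p_adjusted, p.adjust(p, "BH"))
  expect_equal(res$significant, res$p_adjusted <= 0.05)
})
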