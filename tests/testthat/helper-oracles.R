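# Shared oracles and fixture builders (all fixtures generated in code).

# Interval overlap matching: fraction of the longer interval covered.
interval_matched <- function(a_start, a_end, b_start, b_end, min_overlap = 0.8) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  len <- pmax(a_end - a_start, b_end - b_start)
  any(ov / len >= min_overlap)
}

# Recall/precision of detected vs. true intervals at 80% overlap.
match_stats <- function(true_df, det_df, min_overlap = 0.8) {
  recall <- if (nrow(true_df) == 0) 1 else mean(vapply(
    seq_len(nrow(true_df)), function(i) {
      interval_matched(true_df$start_s[i], true_df$end_s[i],
                       det_df$start_s, det_df$end_s, min_overlap)
    }, TRUE))
  precision <- if (nrow(det_df) == 0) 1 else mean(vapply(
    seq_len(nrow(det_df)), function(j) {
      interval_matched(det_df$start_s[j], det_df$end_s[j],
                       true_df$start_s, true_df$end_s, min_overlap)
    }, TRUE))
  c(recall = recall, precision = precision)
}

# Simple FFT periodogram amplitude at integer frequencies (independent of
# the package's multitaper path).
periodogram_amplitude <- function(x, fs, freqs) {
  n <- length(x)
  X <- Mod(fft(x - mean(x)))
  bins <- round(freqs * n / fs) + 1L
  X[bins]
}

# Band power from the raw periodogram (oracle for delta dominance checks).
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(fft(x - mean(x)))^2
  f <- (0:(n - 1)) * fs / n
  sum(P[f >= lo & f <= hi])
}

# A short two-channel record: background plus 7-Hz trains at given times.
make_train_record <- function(total_s, train_starts, train_durs,
                              fs = 200, sigma = 20, ratio = 2.5,
                              fundamental = 7, seed = 1) {
  set.seed(seed)
  amp <- ratio * qnorm(0.975) * sigma
  base <- make_background(total_s, fs, sigma)
  for (i in seq_along(train_starts)) {
    tr <- make_swd_train(train_durs[i], fundamental, amp, fs)
    i0 <- round(train_starts[i] * fs) + 1L
    base[i0:(i0 + length(tr) - 1L)] <- base[i0:(i0 + length(tr) - 1L)] + tr
  }
  eeg_record(base, base + make_background(total_s, fs, sigma / 3),
             sampling_rate = fs, record_id = "fixture")
}
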