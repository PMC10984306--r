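# Synthetic two-channel rodent EEG: spike-and-wave trains, sedation sleep,
# and full dexmedetomidine-like sessions with ground-truth annotations.

# Peak-equivalent amplitude of a Gaussian background of standard deviation
# sigma: the 95th percentile of the rectified signal. Shared convention
# between the generator (scaling discharge peaks relative to background) and
# the detector (background amplitude estimate).
PEAK_FACTOR <- stats::qnorm(0.975)

#' Configuration of a simulated injection session
#'
#' Bundles every tunable of [generate_dex_session()]. Timeline defaults are
#' the reported session statistics of the rat cohort the generator emulates
#' (means with per-animal SDs recovered from SEMs via SD = SEM * sqrt(n),
#' n = 8): a 40-min baseline with spontaneous 5--20 s discharges, an initial
#' absence-status event 2.74 +/- 0.42 min after injection lasting
#' 128 +/- 13.74 s, sedation sleep of 31.43 +/- 2.53 min starting
#' 6.78 +/- 0.78 min after injection, and a second period of status events
#' whose durations fall in 1--2 / 2--5 / >5 min bins with 70:17:14 weights
#' and a grand mean of 170.1 s. Discharge fundamentals slow across phases
#' (6 Hz baseline, 5.9 Hz initial status, 5 Hz post-sleep).
#'
#' @param sampling_rate Hz; must be at least 80 (Nyquist covers 1--40 Hz).
#' @param baseline_duration_s Pre-injection recording length, seconds. The
#'   injection happens at exactly this time.
#' @param sigma_uv RMS of the wake background, microvolts.
#' @param sleep_sigma_uv RMS of the sedation-sleep signal, microvolts. Kept
#'   below twice the wake background so sleep never trips the discharge
#'   amplitude rule.
#' @param initial_status_onset_mean_min,initial_status_onset_sd_min Mean/SD
#'   (minutes after injection) of the initial status onset, truncated to
#'   `initial_status_onset_range_min`.
#' @param initial_status_onset_range_min Truncation range, minutes.
#' @param initial_status_duration_mean_s,initial_status_duration_sd_s Mean/SD
#'   (seconds) of the initial status duration, truncated to
#'   `initial_status_duration_range_s`.
#' @param initial_status_duration_range_s Truncation range, seconds.
#' @param n_initial_status 1 (default) or 2 initial status events.
#' @param sleep_latency_mean_min,sleep_latency_sd_min Mean/SD (minutes after
#'   injection) of sleep onset; the draw is truncated below so sleep always
#'   starts after the last initial status event ends.
#' @param sleep_duration_mean_min,sleep_duration_sd_min Mean/SD (minutes) of
#'   sleep duration, truncated to `sleep_duration_range_min`.
#' @param sleep_duration_range_min Truncation range, minutes.
#' @param second_period_bin_weights Length-3 nonnegative weights of the
#'   1--2 / 2--5 / >5 min duration bins for second-period events.
#' @param second_period_event_mean Mean event count of the second period
#'   (Poisson, at least 1 unless all bin weights are zero).
#' @param second_period_b3_excess_mean_s Mean of the exponential excess over
#'   300 s for >5-min events; 227 s makes the grand mean of second-period
#'   durations equal 170.1 s under the default bin weights.
#' @param second_period_b3_max_s Upper cap (seconds) on >5-min events
#'   (26 min, the longest observed event).
#' @param second_period_gap_min_s,second_period_gap_mean_s Gap between
#'   consecutive second-period events: `gap_min + Exp(mean = gap_mean)`.
#' @param swd_fundamental_hz Named numeric vector with entries `baseline`,
#'   `initial`, `second`: discharge fundamental per phase, Hz.
#' @param amplitude_ratio Per-cycle discharge peak amplitude divided by the
#'   peak-equivalent background amplitude (1.96 * `sigma_uv`). Must exceed
#'   the detector threshold of 2.
#' @param baseline_swd_duration_range_s Range of spontaneous baseline
#'   discharge durations, seconds.
#' @param baseline_swd_gap_min_s,baseline_swd_gap_mean_s Gap between
#'   baseline discharges: `gap_min + Exp(mean = gap_mean)`.
#' @param spindle_density_per_min Sleep-spindle rate during sedation sleep.
#' @param amp_jitter_by_phase Named numeric vector (`baseline`, `initial`,
#'   `second`): scale of the multiplicative per-cycle peak-amplitude
#'   jitter per phase. Baseline and initial-status cycles jitter
#'   symmetrically; second-period cycles jitter upward only (right-skewed,
#'   occasional high-voltage spikes), reproducing the elevated
#'   peak-voltage variance of the post-sleep state without ever dropping
#'   below the nominal amplitude.
#' @param harmonic_attenuation Widening factor of the spike component for
#'   second-period discharges in `[0, 1)`; larger values attenuate the 2f/3f
#'   harmonics, emulating the blunted post-sleep morphology. Set to 0 to
#'   disable.
#' @param second_period_suppressed Logical; `TRUE` zeroes out the second
#'   period (pretreatment-like outcome).
#' @param force_longest_event_s Optional; if non-`NULL`, the longest
#'   second-period event is set to exactly this duration (seconds).
#' @param trailing_s Plain background appended after the last event.
#' @param common_power_frac Fraction of background power shared between the
#'   hemispheres (events and sleep are fully shared); controls baseline
#'   interhemispheric coherence.
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#'
#' @return A list of class `session_config`.
#' @export
session_config <- function(sampling_rate = 200,
                           baseline_duration_s = 2400,
                           sigma_uv = 20,
                           sleep_sigma_uv = 25,
                           initial_status_onset_mean_min = 2.74,
                           initial_status_onset_sd_min = 0.42 * sqrt(8),
                           initial_status_onset_range_min = c(1, 5),
                           initial_status_duration_mean_s = 128,
                           initial_status_duration_sd_s = 13.74 * sqrt(8),
                           initial_status_duration_range_s = c(60, 240),
                           n_initial_status = 1,
                           sleep_latency_mean_min = 6.78,
                           sleep_latency_sd_min = 0.78 * sqrt(8),
                           sleep_duration_mean_min = 31.43,
                           sleep_duration_sd_min = 2.53 * sqrt(8),
                           sleep_duration_range_min = c(20, 42),
                           second_period_bin_weights = c(70, 17, 14),
                           second_period_event_mean = 101 / 8,
                           second_period_b3_excess_mean_s = 227,
                           second_period_b3_max_s = 1560,
                           second_period_gap_min_s = 5,
                           second_period_gap_mean_s = 50,
                           swd_fundamental_hz = c(baseline = 6,
                                                  initial = 5.9,
                                                  second = 5),
                           amplitude_ratio = 2.5,
                           amp_jitter_by_phase = c(baseline = 0.05,
                                                   initial = 0.06,
                                                   second = 0.25),
                           baseline_swd_duration_range_s = c(5, 20),
                           baseline_swd_gap_min_s = 30,
                           baseline_swd_gap_mean_s = 40,
                           spindle_density_per_min = 2,
                           harmonic_attenuation = 0.5,
                           second_period_suppressed = FALSE,
                           force_longest_event_s = NULL,
                           trailing_s = 120,
                           common_power_frac = 0.75,
                           seed = 1L) {
  cfg <- as.list(environment())
  validate_session_config(cfg)
  class(cfg) <- "session_config"
  cfg
}

validate_session_config <- function(cfg) {
  stopifnot(
    cfg$sampling_rate >= 80,
    cfg$baseline_duration_s >= 0,
    cfg$sigma_uv > 0,
    cfg$amplitude_ratio > 1,
    cfg$n_initial_status %in% c(1, 2),
    length(cfg$second_period_bin_weights) == 3,
    all(cfg$second_period_bin_weights >= 0),
    all(cfg$swd_fundamental_hz > 0),
    cfg$trailing_s >= 0,
    cfg$common_power_frac > 0, cfg$common_power_frac <= 1
  )
  if (!cfg$second_period_suppressed &&
      sum(cfg$second_period_bin_weights) == 0 &&
      !is.null(cfg$force_longest_event_s)) {
    stop("cannot force a longest event with all bin weights zero")
  }
  invisible(cfg)
}

#' Band-limited coloured background noise
#'
#' Pink (1/f-amplitude-shaped) Gaussian noise restricted to the 1--40 Hz
#' band, scaled to a target RMS. This is the reference level against which
#' discharge amplitudes are expressed.
#'
#' @param duration_s Segment length, seconds (>= 0).
#' @param sampling_rate Hz.
#' @param sigma_uv Target RMS, microvolts (> 0).
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (used internally by the session generator).
#' @return Numeric vector of `round(duration_s * sampling_rate)` samples,
#'   zero mean.
#' @export
make_background <- function(duration_s, sampling_rate, sigma_uv = 20,
                            seed = NULL) {
  if (duration_s < 0) stop("duration_s must be >= 0")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (sigma_uv <= 0) stop("sigma_uv must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sampling_rate)
  if (n == 0) return(numeric(0))
  w <- stats::rnorm(n)
  x <- fft_band_filter(w, sampling_rate, 1, 40,
                       shape = function(f) 1 / sqrt(pmax(f, 1)))
  x <- x - mean(x)
  r <- sqrt(mean(x^2))
  if (r == 0) return(x)
  x * (sigma_uv / r)
}

# One spike-and-wave cycle evaluated at phase u in [0, 1): a narrow positive
# spike (Gaussian, ~1/5 cycle at default width) followed by a slow negative
# half-wave. Non-sinusoidal, so harmonics at 2f and 3f are present.
swd_cycle_shape <- function(u, spike_width = 0.035) {
  spike <- exp(-0.5 * ((u - 0.1) / spike_width)^2)
  slow <- -0.55 * sin(pi * pmax(0, pmin(1, (u - 0.2) / 0.8)))
  spike + slow
}

#' Synthetic spike-and-wave discharge train
#'
#' Periodic sharp-spike-plus-slow-wave cycles at an exact fundamental
#' frequency (phase-accumulator synthesis, so the periodogram peak falls on
#' the requested frequency) with mild per-cycle amplitude jitter. Harmonics
#' at 2x and 3x the fundamental are present because the cycle is
#' non-sinusoidal.
#'
#' @param duration_s Train length, seconds (>= 0).
#' @param fundamental_hz Cycle rate, Hz; must lie in [1, 11] and below
#'   Nyquist/3 so the third harmonic is representable.
#' @param amplitude_uv Target per-cycle peak amplitude, microvolts.
#' @param sampling_rate Hz.
#' @param spike_width Width of the spike component as a fraction of the
#'   cycle (default 0.035); widening it attenuates the harmonics.
#' @param amp_jitter Scale of the multiplicative per-cycle amplitude
#'   jitter.
#' @param amp_jitter_kind `"symmetric"` (Gaussian around the nominal
#'   amplitude) or `"upward"` (half-Gaussian above it: occasional
#'   high-voltage spikes, right-skewed peak distribution, never below
#'   nominal).
#' @param seed Optional integer seed (`NULL` continues the RNG stream).
#' @return Numeric vector of `round(duration_s * sampling_rate)` samples.
#' @export
#' @examples
#' x <- make_swd_train(10, 7, 100, 200, seed = 1)
#' length(x)
make_swd_train <- function(duration_s, fundamental_hz, amplitude_uv,
                           sampling_rate, spike_width = 0.035,
                           amp_jitter = 0.05,
                           amp_jitter_kind = c("symmetric", "upward"),
                           seed = NULL) {
  amp_jitter_kind <- match.arg(amp_jitter_kind)
  if (duration_s < 0) stop("duration_s must be >= 0")
  if (fundamental_hz < 1 || fundamental_hz > 11) {
    stop("fundamental_hz must lie in [1, 11]")
  }
  if (fundamental_hz > sampling_rate / 6) {
    stop("fundamental above Nyquist/3: third harmonic not representable")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sampling_rate)
  if (n == 0) return(numeric(0))
  t <- (0:(n - 1)) / sampling_rate
  u <- (fundamental_hz * t) %% 1
  cyc_id <- floor(fundamental_hz * t) + 1L
  v <- swd_cycle_shape(u, spike_width)
  # centre and normalise with a dense reference cycle so the scaling does
  # not depend on where the samples fall within the cycle
  ref <- swd_cycle_shape((0:4095) / 4096, spike_width)
  v <- (v - mean(ref)) / max(abs(ref - mean(ref)))
  amps <- if (amp_jitter_kind == "symmetric") {
    1 + stats::rnorm(max(cyc_id), 0, amp_jitter)
  } else {
    1 + abs(stats::rnorm(max(cyc_id), 0, amp_jitter))
  }
  v <- v * amps[cyc_id]
  # emulate the 1-40 Hz acquisition band of the amplifier, then restore the
  # per-cycle peak level (the narrow spike loses out-of-band energy)
  v <- fft_band_filter(v, sampling_rate, 1, 40)
  pk <- stats::median(vapply(split(v, cyc_id), function(s) max(abs(s)),
                             numeric(1)))
  if (pk > 0) v <- v * (amplitude_uv / pk)
  v
}

#' Synthetic sedation-sleep EEG
#'
#' Delta-dominant (1--4 Hz) signal with occasional spindle-like 12--15 Hz
#' transients. Band power in 1--4 Hz exceeds that of every other 4-Hz-wide
#' window in 1--40 Hz.
#'
#' @param duration_s Segment length, seconds (>= 0).
#' @param sampling_rate Hz.
#' @param spindle_density_per_min Expected spindle count per minute (>= 0).
#' @param sigma_uv Target overall RMS, microvolts.
#' @param seed Optional integer seed (`NULL` continues the RNG stream).
#' @return Numeric vector of samples.
#' @export
make_sleep_segment <- function(duration_s, sampling_rate,
                               spindle_density_per_min = 2,
                               sigma_uv = 25, seed = NULL) {
  if (duration_s < 0) stop("duration_s must be >= 0")
  if (spindle_density_per_min < 0) stop("spindle density must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sampling_rate)
  if (n == 0) return(numeric(0))
  broad <- make_background(duration_s, sampling_rate, 0.45 * sigma_uv)
  delta <- fft_band_filter(stats::rnorm(n), sampling_rate, 1, 4,
                           trans_low = 0.3, trans_high = 0.5)
  delta <- delta / sqrt(mean(delta^2)) * 0.89 * sigma_uv
  x <- broad + delta
  n_spindles <- stats::rpois(1, spindle_density_per_min * duration_s / 60)
  if (n_spindles > 0) {
    sp_len <- round(0.8 * sampling_rate)
    for (i in seq_len(n_spindles)) {
      f_sp <- stats::runif(1, 12.5, 15)
      t0 <- stats::runif(1, 0, max(duration_s - 1, 0))
      i0 <- round(t0 * sampling_rate) + 1L
      idx <- i0:min(i0 + sp_len - 1L, n)
      tt <- (seq_along(idx) - 1) / sampling_rate
      env <- sin(pi * (seq_along(idx) - 1) / length(idx))^2
      x[idx] <- x[idx] +
        1.2 * sigma_uv * env * sin(2 * pi * f_sp * tt + stats::runif(1, 0, 2 * pi))
    }
  }
  x
}

#' Simulate a full injection session with ground truth
#'
#' Assembles a two-channel session: pre-injection baseline with spontaneous
#' short discharges, the injection, one (or two) initial absence-status
#' events, a sedation-sleep block, a second period of status events with
#' configurable duration-bin weights, and a trailing baseline. Both channels
#' share the event content (plus partially shared background), so
#' interhemispheric coherence is high during discharges. Identical seeds
#' give bit-identical records and annotations.
#'
#' If the sampled timeline would overflow the nominal session the record is
#' extended (never silently truncating a status event below 60 s); a
#' `session_extended` attribute on the ground truth flags this.
#'
#' @param config A [session_config()].
#' @return A list with elements `record` (an [eeg_record()]) and `truth`
#'   (class `ground_truth`): `events` data.frame (`start_s`, `end_s`,
#'   `kind` in swd/status_initial/status_second, `fundamental_hz`),
#'   `sleep` data.frame (`start_s`, `end_s`), and `injection_time_s`.
#' @export
#' @examples
#' sess <- generate_dex_session(session_config(seed = 42))
#' sess$record
#' head(sess$truth$events)
generate_dex_session <- function(config = session_config()) {
  truth <- sample_session_timeline(config)
  render_session(config, truth)
}

#' Sample only the session timeline (ground truth)
#'
#' Draws the annotation layer of [generate_dex_session()] — event intervals,
#' sleep block, injection time — without rendering any waveform. Useful for
#' checking the generator's timeline statistics cheaply across many seeds.
#' `generate_dex_session()` calls this with the same seed, so the timeline
#' of a rendered session is identical to the one sampled here.
#'
#' @param config A [session_config()].
#' @return A `ground_truth` object (see [generate_dex_session()]).
#' @export
sample_session_timeline <- function(config = session_config()) {
  validate_session_config(config)
  set.seed(config$seed)
  inj <- config$baseline_duration_s
  f0 <- config$swd_fundamental_hz

  events <- list()
  add_event <- function(start, end, kind, fund) {
    events[[length(events) + 1L]] <<-
      data.frame(start_s = start, end_s = end, kind = kind,
                 fundamental_hz = fund, stringsAsFactors = FALSE)
  }

  # --- baseline discharges -------------------------------------------------
  t <- 30
  repeat {
    gap <- config$baseline_swd_gap_min_s +
      stats::rexp(1, 1 / config$baseline_swd_gap_mean_s)
    dur <- stats::runif(1, config$baseline_swd_duration_range_s[1],
                        config$baseline_swd_duration_range_s[2])
    if (t + gap + dur > inj - 30) break
    add_event(t + gap, t + gap + dur, "swd", f0[["baseline"]])
    t <- t + gap + dur
  }

  # --- initial status ------------------------------------------------------
  # truncation to the physiological range would shift the sampled means;
  # adjust the untruncated means so the truncated means stay on target
  onset_mu <- tnorm_mean_adjust(config$initial_status_onset_mean_min,
                                config$initial_status_onset_sd_min,
                                config$initial_status_onset_range_min[1],
                                config$initial_status_onset_range_min[2])
  dur_mu <- tnorm_mean_adjust(config$initial_status_duration_mean_s,
                              config$initial_status_duration_sd_s,
                              config$initial_status_duration_range_s[1],
                              config$initial_status_duration_range_s[2])
  onset_min <- rtnorm(1, onset_mu, config$initial_status_onset_sd_min,
                      config$initial_status_onset_range_min[1],
                      config$initial_status_onset_range_min[2])
  init_start <- inj + onset_min * 60
  init_end <- init_start
  for (i in seq_len(config$n_initial_status)) {
    dur <- rtnorm(1, dur_mu, config$initial_status_duration_sd_s,
                  config$initial_status_duration_range_s[1],
                  config$initial_status_duration_range_s[2])
    add_event(init_start, init_start + dur, "status_initial", f0[["initial"]])
    init_end <- init_start + dur
    init_start <- init_end + stats::runif(1, 5, 15)  # gap before a 2nd event
  }

  # --- sleep ---------------------------------------------------------------
  # sleep follows the initial status after a positive gamma-distributed gap
  # whose moments are matched so the latency (sleep start - injection) has
  # the configured mean and SD
  om <- tnorm_moments(onset_mu, config$initial_status_onset_sd_min,
                      config$initial_status_onset_range_min[1],
                      config$initial_status_onset_range_min[2])
  dm <- tnorm_moments(dur_mu, config$initial_status_duration_sd_s,
                      config$initial_status_duration_range_s[1],
                      config$initial_status_duration_range_s[2])
  gap_mean <- max(config$sleep_latency_mean_min -
                    (om$mean + config$n_initial_status * dm$mean / 60 +
                       (config$n_initial_status - 1) * 10 / 60),
                  0.1)
  gap_var <- max(config$sleep_latency_sd_min^2 - om$var - dm$var / 3600,
                 0.01)
  sleep_gap_min <- stats::rgamma(1, shape = gap_mean^2 / gap_var,
                                 rate = gap_mean / gap_var)
  sleep_dur_mu <- tnorm_mean_adjust(config$sleep_duration_mean_min,
                                    config$sleep_duration_sd_min,
                                    config$sleep_duration_range_min[1],
                                    config$sleep_duration_range_min[2])
  sleep_dur_min <- rtnorm(1, sleep_dur_mu, config$sleep_duration_sd_min,
                          config$sleep_duration_range_min[1],
                          config$sleep_duration_range_min[2])
  sleep_start <- init_end + sleep_gap_min * 60
  sleep_end <- sleep_start + sleep_dur_min * 60

  # --- second period -------------------------------------------------------
  wts <- config$second_period_bin_weights
  sp_durs <- numeric(0)
  if (!config$second_period_suppressed && sum(wts) > 0) {
    n2 <- max(1L, stats::rpois(1, config$second_period_event_mean))
    bins <- sample.int(3, n2, replace = TRUE, prob = wts / sum(wts))
    sp_durs <- vapply(bins, function(b) {
      if (b == 1) stats::runif(1, 60, 120)
      else if (b == 2) stats::runif(1, 120, 300)
      else {
        repeat {
          d <- 300 + stats::rexp(1, 1 / config$second_period_b3_excess_mean_s)
          if (d <= config$second_period_b3_max_s) return(d)
        }
      }
    }, numeric(1))
    if (!is.null(config$force_longest_event_s)) {
      sp_durs[which.max(sp_durs)] <- config$force_longest_event_s
    }
  }
  t <- sleep_end + stats::runif(1, 2, 10)
  for (d in sp_durs) {
    add_event(t, t + d, "status_second", f0[["second"]])
    t <- t + d + config$second_period_gap_min_s +
      stats::rexp(1, 1 / config$second_period_gap_mean_s)
  }
  last_end <- if (length(sp_durs)) max(vapply(events, function(e) e$end_s, 1))
              else sleep_end

  events <- do.call(rbind, events)
  events <- events[order(events$start_s), , drop = FALSE]
  rownames(events) <- NULL

  nominal_end <- inj + 10800  # 3-h post-injection recording
  total_s <- ceiling(max(last_end, sleep_end) + config$trailing_s)
  extended <- total_s > nominal_end

  structure(
    list(events = events,
         sleep = data.frame(start_s = sleep_start, end_s = sleep_end),
         injection_time_s = inj,
         total_s = total_s),
    class = "ground_truth", session_extended = extended
  )
}

# Render the waveform for a sampled timeline; continues the RNG stream left
# by sample_session_timeline() so generate_dex_session() is deterministic.
render_session <- function(config, truth) {
  fs <- config$sampling_rate
  amp <- config$amplitude_ratio * PEAK_FACTOR * config$sigma_uv
  events <- truth$events
  sleep_start <- truth$sleep$start_s
  sleep_end <- truth$sleep$end_s
  total_s <- truth$total_s

  # --- waveform assembly ---------------------------------------------------
  n <- round(total_s * fs)
  common <- make_background(total_s, fs,
                            sqrt(config$common_power_frac) * config$sigma_uv)
  noise_sd <- sqrt(1 - config$common_power_frac) * config$sigma_uv
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    i0 <- round(ev$start_s * fs) + 1L
    dur <- ev$end_s - ev$start_s
    spike_w <- 0.035
    if (ev$kind == "status_second" && config$harmonic_attenuation > 0) {
      spike_w <- 0.035 * (1 + config$harmonic_attenuation)
    }
    phase <- switch(ev$kind, swd = "baseline",
                    status_initial = "initial", status_second = "second")
    tr <- make_swd_train(dur, ev$fundamental_hz, amp, fs,
                         spike_width = spike_w,
                         amp_jitter = config$amp_jitter_by_phase[[phase]],
                         amp_jitter_kind = if (phase == "second") "upward"
                                           else "symmetric")
    idx <- i0:(i0 + length(tr) - 1L)
    common[idx] <- common[idx] + tr
  }
  sl_i0 <- round(sleep_start * fs) + 1L
  sl <- make_sleep_segment(sleep_end - sleep_start, fs,
                           config$spindle_density_per_min,
                           config$sleep_sigma_uv)
  sl_idx <- sl_i0:(sl_i0 + length(sl) - 1L)
  common[sl_idx] <- 0.3 * common[sl_idx] + sl

  left <- common + if (noise_sd > 0) make_background(total_s, fs, noise_sd)
                   else 0
  right <- common + if (noise_sd > 0) make_background(total_s, fs, noise_sd)
                    else 0

  record <- eeg_record(left, right, fs,
                       injection_time_s = truth$injection_time_s,
                       record_id = sprintf("sim-seed%d", config$seed))
  list(record = record, truth = truth)
}
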