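# Absence-status classification, duration bins, sedation-sleep scoring,
# and session phase segmentation.

#' Classify detected discharges as absence-status events
#'
#' A continuous discharge lasting one minute or more is an absence-status
#' event. Returned events carry a duration-bin label: `B1` = \[60, 120) s
#' (1--2 min), `B2` = \[120, 300) s (2--5 min), `B3` = \[300, Inf) s
#' (> 5 min); bins are left-closed. Sub-minute events are dropped,
#' untouched.
#'
#' @param events An `swd_events` data.frame from [detect_swds()] (sorted).
#' @param min_status_s Status threshold, seconds (default 60).
#' @return The qualifying rows with an added `bin` factor column
#'   (`B1`/`B2`/`B3`); class `status_events`.
#' @export
classify_status <- function(events, min_status_s = 60) {
  keep <- events$duration_s >= min_status_s
  out <- events[keep, , drop = FALSE]
  out$bin <- cut(out$duration_s, breaks = c(60, 120, 300, Inf),
                 labels = c("B1", "B2", "B3"), right = FALSE)
  rownames(out) <- NULL
  class(out) <- c("status_events", class(events))
  out
}

#' Count status events per duration bin
#'
#' @param status_events Output of [classify_status()].
#' @return Named integer vector `c(B1 = , B2 = , B3 = )`; sums to the
#'   number of status events.
#' @export
#' @examples
#' ev <- data.frame(start_s = c(0, 200, 900), end_s = c(70, 330, 1300))
#' ev$duration_s <- ev$end_s - ev$start_s
#' bin_durations(classify_status(ev))
bin_durations <- function(status_events) {
  counts <- table(factor(status_events$bin, levels = c("B1", "B2", "B3")))
  stats::setNames(as.integer(counts), c("B1", "B2", "B3"))
}

#' Sleep-scoring configuration
#'
#' @param window_s Spectral window length, seconds.
#' @param step_s Window step, seconds.
#' @param delta_low,delta_high Delta band, Hz.
#' @param total_low,total_high Reference band, Hz.
#' @param delta_fraction_threshold A window is delta-dominant when delta
#'   band power exceeds this fraction of 1--40 Hz power.
#' @param min_sleep_s Minimum reported sleep interval, seconds.
#' @param max_interruption_s Non-dominant stretches up to this long (e.g.
#'   spindles) are absorbed into a surrounding sleep interval.
#' @param window_pass_fraction Required fraction of dominant windows within
#'   a reported interval.
#' @return List of class `sleep_config`.
#' @export
sleep_config <- function(window_s = 10, step_s = 1,
                         delta_low = 1, delta_high = 4,
                         total_low = 1, total_high = 40,
                         delta_fraction_threshold = 0.45,
                         min_sleep_s = 60, max_interruption_s = 10,
                         window_pass_fraction = 0.8) {
  cfg <- as.list(environment())
  stopifnot(cfg$window_s > 0, cfg$step_s > 0,
            cfg$delta_low < cfg$delta_high,
            cfg$delta_fraction_threshold > 0,
            cfg$delta_fraction_threshold < 1,
            cfg$min_sleep_s > 0,
            cfg$window_pass_fraction > 0, cfg$window_pass_fraction <= 1)
  class(cfg) <- "sleep_config"
  cfg
}

#' Detect sedation-sleep intervals
#'
#' Scores sliding windows by the fraction of 1--40 Hz power in the delta
#' band (1--4 Hz) and reports maximal intervals of at least `min_sleep_s`
#' in which at least `window_pass_fraction` of windows are delta-dominant
#' and no detected discharge overlaps. Interval boundaries are placed at
#' window centres, so they track the true transition rather than the
#' window edge.
#'
#' @param record An [eeg_record()].
#' @param events Detected `swd_events` (used to exclude discharge time).
#' @param config A [sleep_config()].
#' @param channel Channel to score.
#' @return data.frame with `start_s`, `end_s` (half-open, non-overlapping,
#'   sorted).
#' @export
detect_sleep <- function(record, events = empty_swd_events(),
                         config = sleep_config(),
                         channel = c("left", "right")) {
  stopifnot(inherits(record, "eeg_record"))
  channel <- match.arg(channel)
  fs <- record$sampling_rate
  wl <- round(config$window_s * fs)
  step <- round(config$step_s * fs)
  if (record$n_samples < wl) {
    stop("insufficient data: record shorter than one sleep window")
  }
  x <- get_channel(record, channel)

  starts <- seq(1L, record$n_samples - wl + 1L, by = step)
  centers <- (starts - 1) / fs + config$window_s / 2
  fgrid <- (0:(wl - 1)) * fs / wl
  rows_delta <- fgrid >= config$delta_low & fgrid <= config$delta_high
  rows_total <- fgrid >= config$total_low & fgrid <= config$total_high
  frac <- numeric(length(starts))
  chunk <- 2000L
  for (c0 in seq(1L, length(starts), by = chunk)) {
    cols <- c0:min(c0 + chunk - 1L, length(starts))
    idx <- outer(seq_len(wl) - 1L, starts[cols], `+`)
    m <- matrix(x[idx], nrow = wl)
    m <- sweep(m, 2, colMeans(m))
    P <- Mod(stats::mvfft(m))^2
    frac[cols] <- colSums(P[rows_delta, , drop = FALSE]) /
      pmax(colSums(P[rows_total, , drop = FALSE]), .Machine$double.eps)
  }
  dom <- frac > config$delta_fraction_threshold

  # windows overlapping a detected discharge can never be sleep
  if (nrow(events) > 0) {
    half <- config$window_s / 2
    for (i in seq_len(nrow(events))) {
      dom[centers > events$start_s[i] - half &
            centers < events$end_s[i] + half] <- FALSE
    }
  }

  # absorb brief interruptions (spindles), then extract long runs
  r <- rle(dom)
  if (length(r$lengths) > 2) {
    for (j in 2:(length(r$values) - 1)) {
      if (!r$values[j] &&
          r$lengths[j] * config$step_s <= config$max_interruption_s &&
          r$values[j - 1] && r$values[j + 1]) {
        r$values[j] <- TRUE
      }
    }
    dom2 <- inverse.rle(list(
      lengths = r$lengths, values = r$values))
  } else {
    dom2 <- dom
  }
  r2 <- rle(dom2)
  ends_i <- cumsum(r2$lengths)
  starts_i <- ends_i - r2$lengths + 1L
  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  for (j in seq_along(r2$values)) {
    if (!r2$values[j]) next
    s <- centers[starts_i[j]] - config$step_s / 2
    e <- centers[ends_i[j]] + config$step_s / 2
    if (e - s < config$min_sleep_s) next
    inside <- centers >= s & centers < e
    if (mean(dom[inside]) < config$window_pass_fraction) next
    out <- rbind(out, data.frame(start_s = s, end_s = e))
  }
  rownames(out) <- NULL
  out
}

#' Segment a session into its phases
#'
#' Splits a drug-injection session into baseline, initial status, sedation
#' sleep, and the second status period, and derives the summary latencies:
#' initial-status onset and sleep latency (minutes after injection), sleep
#' duration (minutes), second-period onset (minutes after injection) and
#' mean second-period event duration (seconds). Status events between the
#' injection and the first sleep interval are the initial status; status
#' events starting after the first sleep interval ends form the second
#' period. A session with no post-injection status events returns empty
#' phases with `NA` latencies and `has_post_injection_status = FALSE`
#' rather than an error (the pretreatment-suppressed outcome).
#'
#' @param status_events Output of [classify_status()], sorted.
#' @param sleep_intervals data.frame from [detect_sleep()].
#' @param injection_time_s Injection time, seconds from record start.
#' @param record Optional [eeg_record()] (used only for its id).
#' @return List of class `session_phases`.
#' @export
segment_session <- function(status_events, sleep_intervals,
                            injection_time_s, record = NULL) {
  stopifnot(is.finite(injection_time_s), injection_time_s >= 0)
  ev <- status_events[status_events$start_s >= injection_time_s, ,
                      drop = FALSE]
  has_sleep <- nrow(sleep_intervals) > 0
  sleep_start <- if (has_sleep) sleep_intervals$start_s[1] else Inf
  sleep_end <- if (has_sleep) sleep_intervals$end_s[1] else Inf

  initial <- ev[ev$start_s < sleep_start, , drop = FALSE]
  second <- ev[ev$start_s >= sleep_end, , drop = FALSE]
  if (nrow(initial)) initial$phase <- "initial"
  if (nrow(second)) second$phase <- "second_period"

  phases <- list(
    record_id = if (!is.null(record)) record$record_id else NA_character_,
    baseline = c(0, injection_time_s),
    injection_time_s = injection_time_s,
    initial_status = initial,
    initial_status_onset_min =
      if (nrow(initial)) (initial$start_s[1] - injection_time_s) / 60
      else NA_real_,
    initial_status_mean_duration_s =
      if (nrow(initial)) mean(initial$duration_s) else NA_real_,
    sleep_intervals = sleep_intervals,
    sleep_latency_min =
      if (has_sleep) (sleep_start - injection_time_s) / 60 else NA_real_,
    sleep_duration_min =
      if (has_sleep) sum(sleep_intervals$end_s - sleep_intervals$start_s) / 60
      else NA_real_,
    second_period = second,
    second_period_onset_min =
      if (nrow(second)) (second$start_s[1] - injection_time_s) / 60
      else NA_real_,
    second_period_mean_duration_s =
      if (nrow(second)) mean(second$duration_s) else NA_real_,
    has_post_injection_status = nrow(ev) > 0
  )
  class(phases) <- "session_phases"
  phases
}

#' @export
print.session_phases <- function(x, ...) {
  cat("<session_phases>\n")
  cat(sprintf("  injection at %.1f s\n", x$injection_time_s))
  cat(sprintf("  initial status: %d event(s), onset %.2f min\n",
              nrow(x$initial_status), x$initial_status_onset_min))
  cat(sprintf("  sleep: latency %.2f min, duration %.2f min\n",
              x$sleep_latency_min, x$sleep_duration_min))
  cat(sprintf("  second period: %d event(s), mean duration %.1f s\n",
              nrow(x$second_period), x$second_period_mean_duration_s))
  invisible(x)
}
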