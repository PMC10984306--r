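# Cohort-level recovery: run the detection/segmentation stack over many
# seeded synthetic sessions and tabulate the recovered timeline statistics.

#' Recover timeline statistics across seeded sessions
#'
#' For each seed: generate a session, band-pass filter, detect discharges,
#' classify status events, score sleep, segment the phases, and collect the
#' recovered summary statistics. This is the workhorse behind the
#' parameter-recovery validation of the whole pipeline: across many seeds
#' the recovered means should match the generator configuration.
#'
#' @param seeds Integer vector of session seeds.
#' @param base_config A [session_config()] whose `seed` is replaced per
#'   session.
#' @param detection A [detection_config()] (defaults to the
#'   injection-session settings of [dex_detection_config()]).
#' @param sleep A [sleep_config()].
#' @param progress Logical; print one dot per session.
#' @return data.frame with one row per session: `seed`,
#'   `initial_onset_min`, `initial_duration_s`, `sleep_latency_min`,
#'   `sleep_duration_min`, `second_n`, `second_sum_s`,
#'   `second_mean_s`, `max_duration_s`. The pooled (grand) mean of
#'   second-period durations is `sum(second_sum_s) / sum(second_n)`.
#' @export
recover_session_statistics <- function(seeds,
                                       base_config = session_config(),
                                       detection = dex_detection_config(),
                                       sleep = sleep_config(),
                                       progress = FALSE) {
  rows <- lapply(seeds, function(s) {
    cfg <- base_config
    cfg$seed <- s
    sess <- generate_dex_session(cfg)
    rec_f <- bandpass(sess$record, detection$bandpass_low,
                      detection$bandpass_high)
    ev <- detect_swds(rec_f, detection, filter = FALSE)
    st <- classify_status(ev)
    sl <- detect_sleep(rec_f, ev, sleep)
    ph <- segment_session(st, sl, sess$record$injection_time_s,
                          record = sess$record)
    if (progress) cat(".")
    data.frame(
      seed = s,
      initial_onset_min = ph$initial_status_onset_min,
      initial_duration_s = ph$initial_status_mean_duration_s,
      sleep_latency_min = ph$sleep_latency_min,
      sleep_duration_min = ph$sleep_duration_min,
      second_n = nrow(ph$second_period),
      second_sum_s = sum(ph$second_period$duration_s),
      second_mean_s = ph$second_period_mean_duration_s,
      max_duration_s = if (nrow(ev)) max(ev$duration_s) else NA_real_
    )
  })
  if (progress) cat("\n")
  do.call(rbind, rows)
}
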