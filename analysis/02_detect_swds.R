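#!/usr/bin/env Rscript
# Detect spike-and-wave discharges in each cohort session and tabulate the
# per-20-min discharge metrics (total duration, count, mean duration).
# Writes: results/events_<seed>.csv, results/swd_metrics.csv

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_cohort.R"))

all_metrics <- list()
for (seed in COHORT_SEEDS) {
  sess <- cohort_session(seed)
  det <- cohort_detect(sess)
  write_events(det$events,
               file.path(RESULTS_DIR, sprintf("events_%d.csv", seed)),
               record_id = sess$record$record_id)
  m <- swd_metrics(det$events, session_length_s = duration_s(sess$record))
  m$seed <- seed
  # time relative to injection for readability
  m$bin_start_min_post_injection <-
    (m$bin_start_s - sess$record$injection_time_s) / 60
  all_metrics[[length(all_metrics) + 1]] <- m
  cat(sprintf("seed %d: %d discharges, total %.0f s\n",
              seed, nrow(det$events), sum(det$events$duration_s)))
}
metrics <- do.call(rbind, all_metrics)
write.csv(metrics, file.path(RESULTS_DIR, "swd_metrics.csv"),
          row.names = FALSE)

# cohort mean of per-bin totals (the time course of discharge burden)
agg <- aggregate(cbind(total_s, count, mean_s) ~ bin_start_min_post_injection,
                 metrics, mean)
cat("\nCohort-mean discharge burden per 20-min bin (min post-injection):\n")
print(round(agg, 1), row.names = FALSE)
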