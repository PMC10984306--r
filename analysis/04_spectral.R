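#!/usr/bin/env Rscript
# Spectral characterisation: multitaper PSDs and interhemispheric
# coherence of one epoch per animal per event type, first-peak
# frequencies, per-frequency Mann-Whitney comparisons with FDR q = 0.01,
# and the per-animal peak-voltage variance test.
# Writes: results/spectra.csv, results/psd_comparisons.csv,
#         results/first_peaks.csv, results/variance_tests.csv

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_cohort.R"))

types <- c("pre_injection", "initial_status", "second_period")
psd_by_type <- setNames(vector("list", 3), types)
coh_rows <- list(); spectra_rows <- list()
first_peaks <- list(); var_rows <- list()

for (seed in COHORT_SEEDS) {
  sess <- cohort_session(seed)
  det <- cohort_detect(sess)
  st <- classify_status(det$events)
  sl <- detect_sleep(det$record, det$events)
  ph <- segment_session(st, sl, sess$record$injection_time_s)
  inj <- sess$record$injection_time_s
  # one event per animal per type: the longest (deterministic stand-in for
  # the blinded manual choice), pre-injection discharges are shorter so the
  # epoch-length floor drops to one epoch length there
  pick <- function(ev, min_s) {
    ev <- ev[ev$duration_s >= min_s, , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    ev[which.max(ev$duration_s), , drop = FALSE]
  }
  chosen <- list(
    pre_injection = pick(det$events[det$events$end_s <= inj, ], 6),
    initial_status = pick(ph$initial_status, 20),
    second_period = pick(ph$second_period, 20)
  )
  peaks_animal <- c(seed = seed)
  for (ty in types) {
    ev <- chosen[[ty]]
    if (is.null(ev)) next
    ep <- select_epochs(ev, det$record, "mid5", min_event_s = 5)
    psd <- multitaper_psd(ep$left, sess$record$sampling_rate)
    coh <- mt_coherence(ep$left, ep$right, sess$record$sampling_rate)
    psd_by_type[[ty]] <- c(psd_by_type[[ty]], list(psd))
    spectra_rows[[length(spectra_rows) + 1]] <- data.frame(
      seed = seed, event_type = ty, epoch_position = "mid5",
      freq_hz = psd$freqs_hz, power = psd$power,
      coherence = coh$coherence)
    pk <- find_spectral_peaks(psd)
    peaks_animal[[paste0(ty, "_first_peak_hz")]] <-
      if (length(pk)) pk[1] else NA_real_
  }
  first_peaks[[length(first_peaks) + 1]] <- as.data.frame(t(peaks_animal))
  # peak-voltage variance across the three chosen events
  if (!any(vapply(chosen, is.null, TRUE))) {
    groups <- lapply(chosen, function(ev) ev$cycle_peak_voltages[[1]])
    vt <- peak_voltage_variance_test(groups)
    var_rows[[length(var_rows) + 1]] <- data.frame(
      seed = seed, statistic = vt$statistic, df = vt$df,
      p_value = vt$p_value)
  }
  cat(sprintf("seed %d: first peaks %s\n", seed,
              paste(round(unlist(peaks_animal[-1]), 1), collapse = " / ")))
}

write.csv(do.call(rbind, spectra_rows),
          file.path(RESULTS_DIR, "spectra.csv"), row.names = FALSE)
fp <- do.call(rbind, first_peaks)
write.csv(fp, file.path(RESULTS_DIR, "first_peaks.csv"), row.names = FALSE)

cat("\nCohort-mean first peak (Hz): pre", round(mean(fp[[2]]), 2),
    "| initial", round(mean(fp[[3]]), 2),
    "| second", round(mean(fp[[4]]), 2), "\n")

# per-frequency comparisons at FDR q = 0.01
cmp_rows <- list()
pairs <- list(c("second_period", "pre_injection"),
              c("initial_status", "pre_injection"),
              c("second_period", "initial_status"))
for (pr in pairs) {
  res <- compare_psd_groups(psd_by_type[[pr[1]]], psd_by_type[[pr[2]]],
                            q = 0.01)
  res$contrast <- paste(pr, collapse = "_vs_")
  cmp_rows[[length(cmp_rows) + 1]] <- res
  cat(sprintf("%s: significant at q=0.01: %s\n", res$contrast[1],
              if (any(res$significant))
                paste(res$freq_hz[res$significant], collapse = ",")
              else "none"))
}
write.csv(do.call(rbind, cmp_rows),
          file.path(RESULTS_DIR, "psd_comparisons.csv"), row.names = FALSE)

# variance tests FDR-corrected across animals
vr <- do.call(rbind, var_rows)
vr <- cbind(vr, fdr_correct(vr$p_value, q = 0.05)[, c("p_adjusted",
                                                      "significant")])
write.csv(vr, file.path(RESULTS_DIR, "variance_tests.csv"),
          row.names = FALSE)
cat(sprintf("\npeak-voltage variance test: %d of %d animals significant (FDR q=0.05), statistic range %.2f-%.2f, df = 2\n",
            sum(vr$significant), nrow(vr), min(vr$statistic),
            max(vr$statistic)))
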