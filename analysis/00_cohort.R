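# Shared cohort definition for the analysis scripts: an 8-animal virtual
# cohort of dexmedetomidine injection sessions, one seed per animal.
# Sourced by the numbered scripts; regenerating a session from its seed is
# bit-reproducible, so scripts can be run independently.

library(swdquant)

COHORT_SEEDS <- 201:208
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

cohort_session <- function(seed) generate_dex_session(session_config(seed = seed))

cohort_detect <- function(sess) {
  det <- dex_detection_config()
  rec_f <- bandpass(sess$record, det$bandpass_low, det$bandpass_high)
  list(record = rec_f,
       events = detect_swds(rec_f, det, filter = FALSE))
}
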