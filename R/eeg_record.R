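#' Two-channel cortical EEG record
#'
#' Container for a synchronized pair of voltage traces (left/right
#' frontoparietal cortex) sampled at a common rate. All time coordinates in
#' the package are seconds from record start and intervals are half-open
#' `[start, end)`.
#'
#' @param left_uv,right_uv Numeric vectors of voltage samples in microvolts;
#'   must have equal length.
#' @param sampling_rate Sampling rate in Hz. Must exceed 80 Hz so the
#'   1--40 Hz analysis band is comfortably below Nyquist.
#' @param injection_time_s Optional drug-injection time in seconds from
#'   record start (`NA` for recordings without an injection).
#' @param record_id Character label for the record.
#'
#' @return An object of class `eeg_record`: a list with elements
#'   `left_uv`, `right_uv`, `sampling_rate`, `injection_time_s`,
#'   `record_id`, and `n_samples`.
#' @export
#' @examples
#' rec <- eeg_record(rnorm(400), rnorm(400), sampling_rate = 200)
#' duration_s(rec)
eeg_record <- function(left_uv, right_uv, sampling_rate,
                       injection_time_s = NA_real_, record_id = "record") {
  if (length(left_uv) != length(right_uv)) {
    stop("left and right channels must have the same length")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 80) {
    stop("sampling_rate must be a single value > 80 Hz")
  }
  if (!is.na(injection_time_s) &&
      (injection_time_s < 0 ||
       injection_time_s > length(left_uv) / sampling_rate)) {
    stop("injection_time_s must lie within the record")
  }
  structure(
    list(
      left_uv = as.numeric(left_uv),
      right_uv = as.numeric(right_uv),
      sampling_rate = sampling_rate,
      injection_time_s = injection_time_s,
      record_id = record_id,
      n_samples = length(left_uv)
    ),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record '%s': 2 x %d samples @ %g Hz (%.1f s)%s>\n",
    x$record_id, x$n_samples, x$sampling_rate,
    x$n_samples / x$sampling_rate,
    if (is.na(x$injection_time_s)) ""
    else sprintf(", injection at %.1f s", x$injection_time_s)
  ))
  invisible(x)
}

#' Record duration in seconds
#'
#' @param record An [eeg_record()].
#' @return Length of the record in seconds.
#' @export
duration_s <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  record$n_samples / record$sampling_rate
}

#' Extract one channel by name
#' @param record An [eeg_record()].
#' @param channel `"left"` or `"right"`.
#' @return Numeric vector of samples in microvolts.
#' @export
get_channel <- function(record, channel = c("left", "right")) {
  channel <- match.arg(channel)
  if (channel == "left") record$left_uv else record$right_uv
}
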