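# File interchange: EDF and a CSV dialect for two-channel records, CSV
# event/metric tables, JSON phase reports.

#' Read a two-channel EEG record
#'
#' Supported formats: EDF (European Data Format, 16-bit; the two signals
#' are taken as left and right channels in file order) and a CSV dialect
#' with header `time_s,left_uv,right_uv` and a uniform sampling grid
#' (validated to 1 ppm).
#'
#' @param path File path.
#' @param format `"edf"` or `"csv"`; default guesses from the extension.
#' @param injection_time_s Optional injection time to attach; for EDF files
#'   written by [write_eeg()] the value stored in the recording-id header
#'   field is recovered automatically.
#' @return An [eeg_record()].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "csv"),
                     injection_time_s = NA_real_) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") read_eeg_edf(path, injection_time_s)
  else read_eeg_csv(path, injection_time_s)
}

read_eeg_csv <- function(path, injection_time_s = NA_real_) {
  dt <- data.table::fread(path)
  if (!identical(names(dt), c("time_s", "left_uv", "right_uv"))) {
    stop("CSV format error: expected header 'time_s,left_uv,right_uv', got '",
         paste(names(dt), collapse = ","), "'")
  }
  if (nrow(dt) < 2) stop("CSV format error: need at least 2 rows")
  d <- diff(dt$time_s)
  dt0 <- d[1]
  bad <- which(abs(d - dt0) > 1e-6 * dt0)
  if (length(bad)) {
    stop(sprintf(
      "CSV format error: non-uniform timestamps, first offending row %d",
      bad[1] + 1L))
  }
  eeg_record(dt$left_uv, dt$right_uv, sampling_rate = 1 / dt0,
             injection_time_s = injection_time_s,
             record_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a two-channel EEG record
#'
#' EDF output uses 16-bit samples, physical unit microvolts, signal labels
#' `EEG L-FP` and `EEG R-FP`, 1-s data records (the last record is
#' zero-padded), and stores the injection time in the recording-id header
#' field so [read_eeg()] round-trips it. CSV output is the
#' `time_s,left_uv,right_uv` dialect.
#'
#' @param record An [eeg_record()].
#' @param path Output path.
#' @param format `"edf"` or `"csv"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(record, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") write_eeg_edf(record, path)
  else write_eeg_csv(record, path)
  invisible(path)
}

write_eeg_csv <- function(record, path) {
  dt <- data.table::data.table(
    time_s = (seq_len(record$n_samples) - 1) / record$sampling_rate,
    left_uv = signif(record$left_uv, 6),
    right_uv = signif(record$right_uv, 6)
  )
  data.table::fwrite(dt, path)
}

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

write_eeg_edf <- function(record, path) {
  fs <- record$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF export needs an integer sampling rate")
  }
  fs <- as.integer(round(fs))
  n_rec <- as.integer(ceiling(record$n_samples / fs))
  ns <- 2L
  phys_max <- max(1, ceiling(max(abs(c(record$left_uv, record$right_uv,
                                       1)))))
  dig_max <- 32767L
  scale <- dig_max / phys_max
  rec_id <- if (is.na(record$injection_time_s)) "Startdate X X X X"
            else sprintf("Startdate X X X X injection_time_s=%g",
                         record$injection_time_s)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(record$record_id, 80),
    pad_field(rec_id, 80),
    pad_field("01.01.24", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4)
  )
  sig_hdr <- function(field, width) {
    paste0(vapply(field, pad_field, "", width = width), collapse = "")
  }
  hdr <- paste0(
    hdr,
    sig_hdr(c("EEG L-FP", "EEG R-FP"), 16),
    sig_hdr(c("", ""), 80),
    sig_hdr(c("uV", "uV"), 8),
    sig_hdr(rep(-phys_max, 2), 8),
    sig_hdr(rep(phys_max, 2), 8),
    sig_hdr(rep(-32768L, 2), 8),
    sig_hdr(rep(dig_max, 2), 8),
    sig_hdr(c("BP:1-40Hz", "BP:1-40Hz"), 80),
    sig_hdr(rep(fs, 2), 8),
    sig_hdr(c("", ""), 32)
  )
  writeChar(hdr, con, eos = NULL)
  quantize <- function(x) {
    n_pad <- n_rec * fs - length(x)
    as.integer(pmax(pmin(round(c(x, numeric(n_pad)) * scale),
                         dig_max), -32768L))
  }
  l <- matrix(quantize(record$left_uv), nrow = fs)
  r <- matrix(quantize(record$right_uv), nrow = fs)
  inter <- rbind(l, r)  # per record: fs left samples then fs right samples
  writeBin(as.integer(inter), con, size = 2, endian = "little")
}

read_eeg_edf <- function(path, injection_time_s = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  invisible(rd(8))                      # version
  record_id <- rd(80)
  rec_field <- rd(80)
  invisible(rd(8)); invisible(rd(8))    # date, time
  invisible(rd(8))                      # header bytes
  invisible(rd(44))
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (ns != 2) {
    stop(sprintf("EDF format error: expected 2 signals, found %d", ns))
  }
  invisible(rd(16 * ns))               # labels
  invisible(rd(80 * ns))
  invisible(rd(8 * ns))                # unit
  phys_min <- as.numeric(c(rd(8), rd(8)))
  phys_max <- as.numeric(c(rd(8), rd(8)))
  dig_min <- as.numeric(c(rd(8), rd(8)))
  dig_max <- as.numeric(c(rd(8), rd(8)))
  invisible(rd(80 * ns))
  spr <- as.integer(c(rd(8), rd(8)))
  invisible(rd(32 * ns))
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  m <- matrix(raw, nrow = sum(spr))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  off <- phys_max - gain * dig_max
  left <- as.vector(m[seq_len(spr[1]), ]) * gain[1] + off[1]
  right <- as.vector(m[spr[1] + seq_len(spr[2]), ]) * gain[2] + off[2]
  if (is.na(injection_time_s) &&
      grepl("injection_time_s=", rec_field, fixed = TRUE)) {
    injection_time_s <-
      as.numeric(sub(".*injection_time_s=([-0-9.eE+]+).*", "\\1", rec_field))
  }
  eeg_record(left, right, sampling_rate = spr[1] / rec_dur,
             injection_time_s = injection_time_s, record_id = record_id)
}

#' Write / read detected events as CSV
#'
#' Columns: `record_id`, `start_s`, `end_s`, `duration_s`,
#' `dominant_frequency_hz`, `n_cycles` (plus `bin`/`phase` when present).
#' Floats are written at 6 significant digits; an empty event list produces
#' a header-only file.
#'
#' @param events `swd_events` / `status_events` data.frame.
#' @param path Output path.
#' @param record_id Label stored in the first column.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, record_id = "record") {
  cols <- intersect(
    c("start_s", "end_s", "duration_s", "dominant_frequency_hz",
      "n_cycles", "bin", "phase"),
    names(events))
  df <- as.data.frame(events)[, cols, drop = FALSE]
  if (!"duration_s" %in% names(df) && nrow(df)) {
    df$duration_s <- df$end_s - df$start_s
  }
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  df <- cbind(record_id = rep(record_id, nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("swd_events", "data.frame")
  df
}

#' Write session phases as JSON
#'
#' All `session_phases` fields are serialised (units are embedded in the
#' field names); event tables become arrays of row objects.
#'
#' @param phases A `session_phases` object from [segment_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phases <- function(phases, path) {
  x <- unclass(phases)
  for (nm in c("initial_status", "second_period")) {
    x[[nm]] <- strip_list_cols(x[[nm]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 8,
                       na = "null", pretty = TRUE)
  invisible(path)
}

strip_list_cols <- function(df) {
  if (is.null(df)) return(df)
  df <- as.data.frame(df)
  df[vapply(df, is.list, TRUE)] <- NULL
  df
}

#' Write spectra in tidy CSV form
#'
#' One row per (record, event type, epoch position, frequency), value
#' column `power` or `coherence`.
#'
#' @param spectra data.frame with at least `freq_hz` and a value column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  num <- vapply(spectra, is.numeric, TRUE)
  spectra[num] <- lapply(spectra[num], signif, digits = 6)
  utils::write.csv(spectra, path, row.names = FALSE)
  invisible(path)
}

#' Write ground-truth annotations as CSV
#'
#' @param truth `ground_truth` object from [generate_dex_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  ev <- truth$events
  ev$start_s <- signif(ev$start_s, 8)
  ev$end_s <- signif(ev$end_s, 8)
  sl <- data.frame(start_s = signif(truth$sleep$start_s, 8),
                   end_s = signif(truth$sleep$end_s, 8),
                   kind = "sleep", fundamental_hz = NA_real_)
  utils::write.csv(rbind(ev, sl), path, row.names = FALSE)
  invisible(path)
}
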