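#' Continuous multi-channel EEG recording of one session phase
#'
#' Container for one phase's raw or filtered EEG: a samples-by-channels matrix
#' in microvolts, the sampling rate, the phase tag, and the nominal (processed)
#' duration the recording should span after resampling.
#'
#' @param data numeric matrix, samples in rows, one column per channel
#'   (column names are the electrode labels, e.g. `Fp1`, `Fp2`, `F5`, `F6`).
#' @param fs sampling rate in Hz.
#' @param phase phase tag (character scalar).
#' @param nominal_s nominal duration in seconds that this recording maps onto
#'   after resampling.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, phase, nominal_s) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (is.null(colnames(data))) stop("channel names required")
  structure(
    list(data = data, fs = fs, phase = phase, nominal_s = nominal_s),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording [%s]: %d samples x %d channels (%s) at %g Hz, %.1f s (nominal %g s)\n",
              x$phase, nrow(x$data), ncol(x$data),
              paste(colnames(x$data), collapse = ","),
              x$fs, nrow(x$data) / x$fs, x$nominal_s))
  invisible(x)
}

rec_duration_s <- function(rec) nrow(rec$data) / rec$fs

#' Write / read a recording as a delimited table with a sidecar
#'
#' The on-disk interchange format is plain text: `<prefix>.csv` holds a header
#' row `time_s,<ch1>,...` with amplitudes in microvolts, and `<prefix>.yaml`
#' holds the metadata (sampling rate, phase, nominal duration, channels).
#'
#' @param rec an [eeg_recording()].
#' @param prefix file path prefix (without extension).
#' @return `write_recording` returns `prefix` invisibly; `read_recording`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(rec, prefix) {
  tab <- data.frame(time_s = (seq_len(nrow(rec$data)) - 1) / rec$fs, rec$data,
                    check.names = FALSE)
  utils::write.csv(tab, paste0(prefix, ".csv"), row.names = FALSE)
  yaml::write_yaml(
    list(sampling_rate_hz = rec$fs, phase = rec$phase,
         nominal_duration_s = rec$nominal_s,
         channels = colnames(rec$data)),
    paste0(prefix, ".yaml")
  )
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  tab <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  dat <- as.matrix(tab[, meta$channels, drop = FALSE])
  eeg_recording(dat, fs = meta$sampling_rate_hz, phase = meta$phase,
                nominal_s = meta$nominal_duration_s)
}

#' Write / read an SPSL survey series as a delimited table
#'
#' Columns: `survey_id` (T1..T8), `time_s` (session time of the answer) and
#' `spsl` (integer 1-5).
#'
#' @param surveys a data.frame as produced by [simulate_session()] (the
#'   `surveys` element of its ground truth) or [survey_series()].
#' @param path file path.
#' @export
write_surveys <- function(surveys, path) {
  utils::write.csv(surveys[, c("survey_id", "time_s", "spsl")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_surveys
#' @export
read_surveys <- function(path) {
  survey_series(utils::read.csv(path))
}
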