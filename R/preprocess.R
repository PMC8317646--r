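#' Remove mains interference with a band-stop (notch) filter
#'
#' Applies a 2nd-order Butterworth band-stop filter with stopband 48-52 Hz,
#' forward and backward (zero phase), to every channel. Power at 50 Hz is
#' attenuated by far more than 20 dB while the EEG passband is left intact.
#'
#' @param rec an [eeg_recording()] sampled above 104 Hz.
#' @return The filtered recording.
#' @export
notch_filter <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 104) stop("sampling rate too low for a 48-52 Hz stopband")
  if (!all(is.finite(rec$data))) stop("recording contains non-finite values")
  flt <- signal::butter(2, c(48, 52) / (rec$fs / 2), type = "stop")
  rec$data <- apply(rec$data, 2, function(x) signal::filtfilt(flt, x))
  rec
}

#' Retain EEG spectral content with a zero-phase Butterworth bandpass
#'
#' 4th-order Butterworth design with passband 2-48 Hz, applied
#' forward-backward so the output has no phase shift (effective 8th-order
#' magnitude response). Drift below 1 Hz and content above 60 Hz are
#' suppressed by more than 20 dB.
#'
#' @inheritParams notch_filter
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 104) stop("sampling rate too low for a 2-48 Hz passband")
  if (!all(is.finite(rec$data))) stop("recording contains non-finite values")
  flt <- signal::butter(4, c(2, 48) / (rec$fs / 2), type = "pass")
  rec$data <- apply(rec$data, 2, function(x) signal::filtfilt(flt, x))
  rec
}

# Fourier-domain resampling of one channel to exactly n_out samples.
# Spectral content below the output Nyquist is preserved; the signal is
# assumed already band-limited well below it (it has been bandpassed to
# 2-48 Hz by the time this runs).
resample_fft <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  k <- (min(n_in, n_out) - 1) %/% 2  # positive bins strictly below Nyquist
  Y[1] <- X[1]
  if (k > 0) {
    Y[1 + seq_len(k)] <- X[1 + seq_len(k)]
    Y[n_out + 1 - seq_len(k)] <- X[n_in + 1 - seq_len(k)]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

#' Resample a recording to its nominal duration
#'
#' Recording onsets were marked manually, so recorded durations differ from the
#' phase's theoretical span by a few seconds. This maps the recording onto
#' exactly `nominal_s * fs` samples via Fourier-domain resampling, which
#' preserves band powers of in-band content to well under 2%.
#'
#' @param rec an [eeg_recording()].
#' @param tol maximum tolerated relative deviation of the recorded duration
#'   from the nominal duration (default 10%); larger deviations signal a
#'   corrupt recording and raise an error.
#' @return The recording with exactly `nominal_s * fs` samples.
#' @export
resample_to_nominal <- function(rec, tol = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- rec_duration_s(rec)
  if (abs(dur - rec$nominal_s) / rec$nominal_s > tol)
    stop(sprintf("recording spans %.1f s but nominal is %g s: corrupt recording",
                 dur, rec$nominal_s))
  n_out <- round(rec$nominal_s * rec$fs)
  rec$data <- apply(rec$data, 2, resample_fft, n_out = n_out)
  rec
}

#' Extract the central window of a recording
#'
#' Only the central minute of the final eyes-closed rest is processed;
#' `extract_central_minute()` returns the centered 60-s window of a recording
#' (a recording of exactly 60 s is returned unchanged).
#'
#' @param rec an [eeg_recording()].
#' @param dur_s window length in seconds (default 60).
#' @return The windowed recording, with `nominal_s` set to `dur_s`.
#' @export
extract_central_minute <- function(rec, dur_s = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_win <- round(dur_s * rec$fs)
  n <- nrow(rec$data)
  if (n < n_win)
    stop(sprintf("recording shorter than %g s", dur_s))
  start <- floor((n - n_win) / 2)
  rec$data <- rec$data[start + seq_len(n_win), , drop = FALSE]
  rec$nominal_s <- dur_s
  rec
}

#' Split a recording into consecutive 2-s epochs
#'
#' Divides a resampled recording into non-overlapping, consecutive epochs of
#' `epoch_s` seconds. For the nominal schedule this yields 180 epochs for the
#' 6-min stress test, 150 for the 5-min relaxation and 30 for the central rest
#' minute — 360 per session.
#'
#' @param rec a resampled [eeg_recording()].
#' @param epoch_s epoch length in seconds (default 2).
#' @return An object of class `epoch_array`: list with `epochs` (array
#'   `n_epochs x n_channels x samples_per_epoch`), `mask` (logical per epoch,
#'   `TRUE` for zeroed outlier epochs), `channels`, `phase`, `fs`, `epoch_s`.
#' @export
epoch_recording <- function(rec, epoch_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- round(epoch_s * rec$fs)
  n <- nrow(rec$data)
  if (n %% spe != 0)
    stop("recording length is not a multiple of the epoch length; resample first")
  n_ep <- n %/% spe
  # samples x channels -> epochs x channels x samples
  ep <- aperm(array(rec$data, dim = c(spe, n_ep, ncol(rec$data))), c(2, 3, 1))
  structure(
    list(epochs = ep, mask = rep(FALSE, n_ep), channels = colnames(rec$data),
         phase = rec$phase, fs = rec$fs, epoch_s = epoch_s),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("Epoch array [%s]: %d epochs x %d channels x %d samples (%d masked)\n",
              x$phase, dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              sum(x$mask)))
  invisible(x)
}

#' Zero epochs exceeding an amplitude threshold
#'
#' Epochs whose absolute amplitude exceeds `threshold_uv` on any channel are
#' tagged as outliers and zeroed across all channels; the epoch mask records
#' them. Raising the threshold can only reduce the number of masked epochs.
#'
#' @param ep an `epoch_array` (amplitudes in uV, post-filtering, before
#'   standardization).
#' @param threshold_uv amplitude threshold in uV (default 75).
#' @return The epoch array with outlier epochs zeroed and `mask` updated.
#' @export
zero_outlier_epochs <- function(ep, threshold_uv = 75) {
  stopifnot(inherits(ep, "epoch_array"))
  peak <- apply(abs(ep$epochs), 1, max)
  bad <- peak > threshold_uv
  ep$epochs[bad, , ] <- 0
  ep$mask <- ep$mask | bad
  ep
}

#' Detrend and standardize every epoch
#'
#' Per epoch and channel, removes the least-squares straight-line fit, then
#' subtracts the mean and divides by the standard deviation, so every
#' non-masked channel-epoch ends with mean 0 and standard deviation 1 (to
#' within 1e-9). Masked (zeroed) epochs are passed through untouched. An epoch
#' that is constant after detrending (e.g. a pure ramp) has no defined
#' standardization; it is zeroed and added to the outlier mask.
#'
#' @param ep an `epoch_array` with outliers already zeroed.
#' @return The standardized epoch array.
#' @export
detrend_standardize <- function(ep) {
  stopifnot(inherits(ep, "epoch_array"))
  d <- dim(ep$epochs)
  n_ep <- d[1]; n_ch <- d[2]; spe <- d[3]
  # rows = (epoch, channel), columns = samples
  X <- matrix(aperm(ep$epochs, c(3, 1, 2)), nrow = spe)  # spe x (n_ep*n_ch)
  X <- t(X)
  tc <- seq_len(spe) - (spe + 1) / 2
  slope <- (X %*% tc) / sum(tc^2)
  resid <- X - rowMeans(X) - tcrossprod(as.vector(slope), tc)
  sdv <- sqrt(rowSums(resid^2) / (spe - 1))
  live <- matrix(rep(!ep$mask, n_ch), ncol = 1)
  degen <- sdv < 1e-12 & live
  sdv[sdv < 1e-12] <- 1
  Z <- resid / sdv
  Z[as.vector(degen), ] <- 0
  # any degenerate channel masks the whole epoch
  degen_ep <- apply(matrix(degen, n_ep, n_ch), 1, any)
  out <- aperm(array(t(Z), dim = c(spe, n_ep, n_ch)), c(2, 3, 1))
  out[ep$mask | degen_ep, , ] <- 0
  ep$epochs <- out
  ep$mask <- ep$mask | degen_ep
  ep
}

#' Run the full preprocessing chain on one phase recording
#'
#' Applies, in order: notch filter, bandpass filter, central-window extraction
#' (when the recording spans more than `processed_s`), resampling to the
#' nominal length, epoching, outlier zeroing, detrending and standardization.
#'
#' @param rec an [eeg_recording()].
#' @param processed_s seconds of the recording that enter the analysis
#'   (defaults to the recording's nominal duration; pass 60 for a 2-min final
#'   rest to keep only its central minute).
#' @param threshold_uv outlier amplitude threshold in uV.
#' @param epoch_s epoch length in seconds.
#' @return An `epoch_array` of standardized epochs.
#' @export
preprocess_recording <- function(rec, processed_s = rec$nominal_s,
                                 threshold_uv = 75, epoch_s = 2) {
  rec <- bandpass_filter(notch_filter(rec))
  if (processed_s < rec$nominal_s)
    rec <- extract_central_minute(rec, dur_s = processed_s)
  rec <- resample_to_nominal(rec)
  ep <- epoch_recording(rec, epoch_s = epoch_s)
  detrend_standardize(zero_outlier_epochs(ep, threshold_uv = threshold_uv))
}

#' Preprocess all phase recordings of a session
#'
#' @param recordings named list of [eeg_recording()]s, one per schedule phase.
#' @param schedule the [session_schedule()] giving each phase's processed
#'   duration.
#' @param threshold_uv outlier amplitude threshold in uV.
#' @return Named list of `epoch_array`s in schedule phase order.
#' @export
preprocess_session <- function(recordings, schedule, threshold_uv = 75) {
  stopifnot(inherits(schedule, "session_schedule"))
  out <- list()
  for (p in seq_len(nrow(schedule$phases))) {
    ph <- schedule$phases[p, ]
    rec <- recordings[[ph$name]]
    if (is.null(rec)) stop("missing recording for phase ", ph$name)
    out[[ph$name]] <- preprocess_recording(
      rec, processed_s = ph$nominal_s, threshold_uv = threshold_uv,
      epoch_s = schedule$epoch_s
    )
  }
  out
}
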