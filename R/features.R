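#' Canonical EEG frequency bands
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz` for the Delta
#'   (1-4 Hz), Theta (4-8 Hz), Alpha (8-13 Hz), Beta (13-25 Hz) and Gamma
#'   (25-45 Hz) bands, in ascending order.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
    low_hz = c(1, 4, 8, 13, 25),
    high_hz = c(4, 8, 13, 25, 45),
    stringsAsFactors = FALSE
  )
}

#' Tukey (tapered cosine) window
#'
#' @param n window length in samples.
#' @param alpha fraction of the window inside the cosine taper (0 gives a
#'   rectangular window, 1 a Hann window).
#' @return Numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.25) {
  stopifnot(n >= 1, alpha >= 0, alpha <= 1)
  if (alpha == 0) return(rep(1, n))
  w <- rep(1, n)
  x <- (seq_len(n) - 1) / (n - 1)
  lo <- x < alpha / 2
  hi <- x >= 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  w
}

# One-sided windowed periodogram of each column of a samples x series matrix.
# Returns list(freq_hz, psd) with psd in power per Hz, normalized so that the
# integral of the PSD recovers the windowed signal's mean-square power.
windowed_periodogram <- function(X, fs, taper_alpha = 0.25) {
  n <- nrow(X)
  w <- tukey_window(n, taper_alpha)
  S <- Mod(stats::mvfft(X * w))^2
  half <- n %/% 2
  scale <- 2 / (fs * sum(w^2))
  psd <- S[seq_len(half + 1), , drop = FALSE] * scale
  psd[1, ] <- psd[1, ] / 2
  if (n %% 2 == 0) psd[half + 1, ] <- psd[half + 1, ] / 2
  list(freq_hz = (0:half) * fs / n, psd = psd)
}

# Trapezoidal integration weights for the PSD bins whose centers fall in
# [low, high); returns a weight vector over all bins.
band_weights <- function(freq_hz, low, high) {
  idx <- which(freq_hz >= low & freq_hz < high)
  w <- numeric(length(freq_hz))
  if (length(idx) >= 2) {
    df <- diff(freq_hz[idx])
    w[idx[-length(idx)]] <- w[idx[-length(idx)]] + df / 2
    w[idx[-1]] <- w[idx[-1]] + df / 2
  }
  w
}

#' Per-epoch, per-channel spectral band powers
#'
#' Estimates, for every epoch and channel, the power spectral density of the
#' Tukey-windowed epoch (single-segment periodogram; the taper eases edge
#' effects) and integrates it over each canonical band by the trapezoidal rule
#' over the bins whose centers fall within `[low, high)`. Zeroed epochs yield
#' zero power in every band.
#'
#' @param ep a standardized `epoch_array` (see [detrend_standardize()]).
#' @param taper_alpha Tukey taper fraction (default 0.25).
#' @param bands band table as returned by [eeg_bands()].
#' @return Array `n_epochs x n_channels x n_bands` with dimnames.
#' @export
epoch_band_powers <- function(ep, taper_alpha = 0.25, bands = eeg_bands()) {
  stopifnot(inherits(ep, "epoch_array"))
  d <- dim(ep$epochs)
  n_ep <- d[1]; n_ch <- d[2]; spe <- d[3]
  X <- matrix(aperm(ep$epochs, c(3, 1, 2)), nrow = spe)  # spe x (n_ep*n_ch)
  pg <- windowed_periodogram(X, ep$fs, taper_alpha)
  W <- vapply(seq_len(nrow(bands)),
              function(b) band_weights(pg$freq_hz, bands$low_hz[b], bands$high_hz[b]),
              numeric(length(pg$freq_hz)))
  bp <- crossprod(pg$psd, W)  # (n_ep*n_ch) x n_bands
  array(bp, dim = c(n_ep, n_ch, nrow(bands)),
        dimnames = list(NULL, ep$channels, bands$name))
}

#' Relative gamma stress index
#'
#' `RG = P_Gamma / (P_Alpha + P_Theta)`. A zeroed epoch has all-zero band
#' powers and an undefined ratio; it is mapped to 0 so the feature matrix
#' stays dense (the epoch remains flagged in the outlier mask).
#'
#' @param p_gamma,p_alpha,p_theta channel-averaged band powers (vectors).
#' @return Numeric vector of RG values.
#' @export
relative_gamma <- function(p_gamma, p_alpha, p_theta) {
  stopifnot(all(p_gamma >= 0), all(p_alpha >= 0), all(p_theta >= 0))
  den <- p_alpha + p_theta
  ifelse(den > 0, p_gamma / den, 0)
}

#' Frontal alpha asymmetry
#'
#' `AA = P_Alpha(F6) - P_Alpha(F5)`: right-minus-left frontal alpha power, a
#' lateralization index of affective state.
#'
#' @param p_alpha_f6,p_alpha_f5 per-channel Alpha powers (vectors).
#' @return Numeric vector of signed differences.
#' @export
alpha_asymmetry <- function(p_alpha_f6, p_alpha_f5) {
  stopifnot(all(p_alpha_f6 >= 0), all(p_alpha_f5 >= 0))
  p_alpha_f6 - p_alpha_f5
}

feature_names <- function() {
  c("P_Delta", "P_Theta", "P_Alpha", "P_Beta", "P_Gamma", "RG", "AA")
}

#' Assemble the per-epoch feature matrix for one phase
#'
#' Builds the seven spectral features from the per-channel band powers: the
#' five channel-averaged band powers, the relative gamma (computed from the
#' channel-averaged powers) and the alpha asymmetry (from the F6 and F5 Alpha
#' powers).
#'
#' @param bp band-power array from [epoch_band_powers()] (requires channels
#'   `F5` and `F6`).
#' @param phase phase tag stored in the epoch timeline.
#' @param epoch_s epoch length in seconds.
#' @return An object of class `feature_matrix`: list with `values`
#'   (`n_epochs x 7` matrix, columns `P_Delta`..`P_Gamma`, `RG`, `AA`),
#'   `phase` and `epoch_start_s` vectors (per row; times are phase-relative).
#' @export
assemble_features <- function(bp, phase = "session", epoch_s = 2) {
  ch <- dimnames(bp)[[2]]
  if (!all(c("F5", "F6") %in% ch))
    stop("channels F5 and F6 are required for alpha asymmetry")
  pavg <- apply(bp, c(1, 3), mean)
  vals <- cbind(
    pavg[, c("Delta", "Theta", "Alpha", "Beta", "Gamma"), drop = FALSE],
    RG = relative_gamma(pavg[, "Gamma"], pavg[, "Alpha"], pavg[, "Theta"]),
    AA = alpha_asymmetry(bp[, "F6", "Alpha"], bp[, "F5", "Alpha"])
  )
  colnames(vals) <- feature_names()
  structure(
    list(values = vals, phase = rep(phase, nrow(vals)),
         epoch_start_s = (seq_len(nrow(vals)) - 1) * epoch_s),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d epochs x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$phase), collapse = ", ")))
  invisible(x)
}

#' Smooth features with a centered moving average
#'
#' Replaces every value by the mean over a centered window of up to
#' `window_s / epoch_s` epochs (15 for the default 30-s window on 2-s
#' epochs), per column and per phase; windows shrink at phase boundaries so
#' the output keeps the input's shape without phase lag.
#'
#' @param fm a `feature_matrix`.
#' @param window_s smoothing window in seconds (default 30).
#' @param epoch_s epoch length in seconds.
#' @return The smoothed `feature_matrix`.
#' @export
smooth_features <- function(fm, window_s = 30, epoch_s = 2) {
  stopifnot(inherits(fm, "feature_matrix"))
  w <- round(window_s / epoch_s)
  if (w < 1) stop("smoothing window must cover at least one epoch")
  if (w == 1) return(fm)
  for (ph in unique(fm$phase)) {
    rows <- which(fm$phase == ph)
    fm$values[rows, ] <- apply(fm$values[rows, , drop = FALSE], 2, function(x)
      zoo::rollapply(x, width = w, FUN = mean, partial = TRUE, align = "center"))
  }
  fm
}

#' Extract the smoothed session feature matrix
#'
#' Runs band-power estimation, feature assembly and per-phase smoothing on each
#' phase's epochs and concatenates the rows in session order, yielding the
#' `n_epochs x 7` session feature matrix (360 x 7 for the nominal schedule).
#'
#' @param epochs_by_phase named list of standardized `epoch_array`s in session
#'   order (see [preprocess_session()]).
#' @param window_s smoothing window in seconds.
#' @param taper_alpha Tukey taper fraction for the PSD estimate.
#' @return A `feature_matrix` covering the session, with an extra element
#'   `mask`: the concatenated outlier mask.
#' @export
extract_features <- function(epochs_by_phase, window_s = 30,
                             taper_alpha = 0.25) {
  parts <- lapply(epochs_by_phase, function(ep) {
    bp <- epoch_band_powers(ep, taper_alpha = taper_alpha)
    smooth_features(assemble_features(bp, phase = ep$phase,
                                      epoch_s = ep$epoch_s),
                    window_s = window_s, epoch_s = ep$epoch_s)
  })
  fm <- structure(
    list(values = do.call(rbind, lapply(parts, `[[`, "values")),
         phase = unlist(lapply(parts, `[[`, "phase"), use.names = FALSE),
         epoch_start_s = unlist(lapply(parts, `[[`, "epoch_start_s"),
                                use.names = FALSE),
         mask = unlist(lapply(epochs_by_phase, `[[`, "mask"),
                       use.names = FALSE)),
    class = "feature_matrix"
  )
  rownames(fm$values) <- NULL
  fm
}

#' Write / read a feature matrix as a delimited table
#'
#' Columns: `phase`, `epoch_start_s`, then the seven features.
#'
#' @param fm a `feature_matrix`.
#' @param path file path.
#' @export
write_feature_matrix <- function(fm, path) {
  tab <- data.frame(phase = fm$phase, epoch_start_s = fm$epoch_start_s,
                    fm$values, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  structure(
    list(values = as.matrix(tab[, feature_names(), drop = FALSE]),
         phase = tab$phase, epoch_start_s = tab$epoch_start_s),
    class = "feature_matrix"
  )
}
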