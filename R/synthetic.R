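#' Configuration for the synthetic session generator
#'
#' Parameterizes the generator that stands in for real stress-relax session
#' recordings: per-band baseline power, the coupling of each band's power to
#' the instantaneous stress level, mains contamination, sporadic high-amplitude
#' artifact epochs, survey reporting noise and recording-length jitter.
#'
#' The EEG is synthesized as a sum of band-limited noise components whose
#' per-band variance follows `baseline * (1 + coupling * s(t))`, where `s(t)`
#' is the ground-truth stress trajectory normalized to `[0, 1]`. Defaults give
#' a background amplitude of roughly 9-10 uV RMS, gamma/beta power rising and
#' alpha/theta power falling with stress — the direction reported for
#' relative-gamma and alpha-band stress markers.
#'
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @param band_baseline_uv2 named numeric, baseline power per band (uV^2).
#' @param coupling named numeric in `(-1, Inf)`, per-band gain applied to the
#'   normalized stress level (positive for Gamma/Beta, negative for Alpha by
#'   default).
#' @param line_amp_uv amplitude of the 50 Hz mains sinusoid (uV).
#' @param artifact_prob per-epoch probability of injecting an artifact burst.
#' @param artifact_uv peak amplitude of injected artifacts; must exceed the
#'   75 uV outlier threshold so artifacts are detectable downstream.
#' @param survey_jitter_prob probability that a survey answer is perturbed by
#'   plus/minus 1 before clipping to the 1-5 scale (reporting noise).
#' @param length_jitter_s half-width (s) of the uniform jitter applied to each
#'   recording's duration, emulating manually marked recording boundaries.
#' @param alpha_asym_ratio multiplicative factor on F6 alpha power relative to
#'   F5 (1 = symmetric).
#' @param trajectory_anchors optional data.frame (`time_s`, `stress`) of
#'   piecewise-linear anchors for the ground-truth trajectory; when `NULL`,
#'   anchors are drawn per seed (start 1.2-2.2, MIST peak 4.2-5, relax decay
#'   back toward 1-2.2).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 0,
                         band_baseline_uv2 = c(Delta = 20, Theta = 15,
                                               Alpha = 25, Beta = 15,
                                               Gamma = 10),
                         coupling = c(Delta = 0, Theta = -0.2, Alpha = -0.4,
                                      Beta = 0.8, Gamma = 1.5),
                         line_amp_uv = 20,
                         artifact_prob = 0.02,
                         artifact_uv = 150,
                         survey_jitter_prob = 0.1,
                         length_jitter_s = 3,
                         alpha_asym_ratio = 1,
                         trajectory_anchors = NULL) {
  if (!all(is.finite(coupling))) stop("coupling must be finite")
  if (any(coupling <= -1))
    stop("coupling must exceed -1 so band variances stay positive")
  if (artifact_prob > 0 && artifact_uv <= 75)
    stop("artifact amplitude must exceed the 75 uV outlier threshold")
  if (!is.null(trajectory_anchors)) {
    stopifnot(is.data.frame(trajectory_anchors),
              all(c("time_s", "stress") %in% names(trajectory_anchors)))
    if (any(trajectory_anchors$stress < 1 | trajectory_anchors$stress > 5))
      stop("trajectory anchors must lie in [1, 5]")
  }
  structure(
    list(seed = seed, band_baseline_uv2 = band_baseline_uv2,
         coupling = coupling, line_amp_uv = line_amp_uv,
         artifact_prob = artifact_prob, artifact_uv = artifact_uv,
         survey_jitter_prob = survey_jitter_prob,
         length_jitter_s = length_jitter_s,
         alpha_asym_ratio = alpha_asym_ratio,
         trajectory_anchors = trajectory_anchors),
    class = "synth_config"
  )
}

# Evaluate a function under a temporary RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Nearest length whose largest prime factor is <= 127, so the mixed-radix FFT
# stays fast regardless of the jittered recording length (the adjustment is
# at most a few tens of samples, i.e. well under 0.2 s at 256 Hz).
fft_friendly_length <- function(n) {
  smooth <- function(m) {
    for (p in c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L,
                41L, 43L, 47L, 53L, 59L, 61L, 67L, 71L, 73L, 79L, 83L,
                89L, 97L, 101L, 103L, 107L, 109L, 113L, 127L))
      while (m %% p == 0L) m <- m %/% p
    m == 1L
  }
  for (d in 0:1000) {
    if (smooth(n + d)) return(n + d)
    if (d > 0 && n - d > 0 && smooth(n - d)) return(n - d)
  }
  n
}

# Band-limited Gaussian noise of length n: white noise whose Fourier
# coefficients outside [lo, hi] Hz are zeroed. Unit variance on return.
band_noise <- function(n, fs, lo, hi) {
  m <- fft_friendly_length(n)
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

# Raised-cosine windowed 10 Hz burst used as an injected artifact.
artifact_burst <- function(fs, dur_s = 0.5, amp = 150) {
  t <- seq(0, dur_s, by = 1 / fs)
  amp * 0.5 * (1 - cos(2 * pi * t / dur_s)) * sin(2 * pi * 10 * t)
}

#' Simulate one stress-relax session
#'
#' Generates one EEG recording per phase of `schedule` (4 channels Fp1, Fp2,
#' F5, F6 at the schedule's sampling rate) together with the ground truth: a
#' per-epoch stress trajectory, the eight survey answers and the session epoch
#' indices at which artifacts were injected.
#'
#' The trajectory is piecewise linear through anchors (low at session start,
#' peak at the end of the stress test, decaying through relaxation), sampled at
#' epoch midpoints. Recordings span their phase's recorded duration plus a
#' uniform jitter (the final rest records 120 s of which only the central
#' minute is processed); band powers track the trajectory; a 50 Hz sinusoid
#' and sporadic >75 uV artifact bursts (confined to the central half of their
#' epoch, on one random channel) are added on top.
#'
#' @param schedule a [session_schedule()].
#' @param config a [synth_config()].
#' @return A list with elements `recordings` (named list of
#'   [eeg_recording()]s, one per phase) and `truth` (list: `trajectory`
#'   length-360 numeric, `surveys` data.frame `survey_id`/`time_s`/`spsl`,
#'   `artifact_epochs` 0-based session epoch indices, `anchors`).
#' @examples
#' sess <- simulate_session(build_default_schedule(), synth_config(seed = 1))
#' names(sess$recordings)
#' @export
simulate_session <- function(schedule, config = synth_config()) {
  stopifnot(inherits(schedule, "session_schedule"),
            inherits(config, "synth_config"))
  with_seed(config$seed, {
    fs <- schedule$fs
    bands <- eeg_bands()
    onsets <- phase_onsets(schedule)
    counts <- phase_epoch_counts(schedule)
    total_s <- sum(schedule$phases$nominal_s)

    anchors <- config$trajectory_anchors
    if (is.null(anchors)) {
      ends <- cumsum(schedule$phases$nominal_s)
      anchors <- data.frame(
        time_s = c(0, ends[1], ends[2], ends[3]),
        stress = c(stats::runif(1, 1.2, 2.2),
                   stats::runif(1, 4.2, 5.0),
                   stats::runif(1, 1.4, 2.2),
                   NA)
      )
      anchors$stress[4] <- max(1, anchors$stress[3] - stats::runif(1, 0, 0.4))
    }
    traj_fun <- stats::approxfun(anchors$time_s, anchors$stress, rule = 2)

    mids <- (seq_len(sum(counts)) - 0.5) * schedule$epoch_s
    trajectory <- pmin(5, pmax(1, traj_fun(mids)))

    t_surv <- survey_session_times(schedule)
    ans <- round(traj_fun(t_surv))
    jit <- stats::runif(length(ans)) < config$survey_jitter_prob
    ans[jit] <- ans[jit] + sample(c(-1L, 1L), sum(jit), replace = TRUE)
    ans <- as.integer(pmin(5L, pmax(1L, ans)))
    surveys <- data.frame(survey_id = names(t_surv),
                          time_s = as.numeric(t_surv), spsl = ans)

    channels <- c("Fp1", "Fp2", "F5", "F6")
    recordings <- list()
    artifact_epochs <- integer(0)
    epoch_offset <- 0L

    for (p in seq_len(nrow(schedule$phases))) {
      ph <- schedule$phases[p, ]
      rec_s <- ph$recorded_s
      actual_s <- rec_s + stats::runif(1, -config$length_jitter_s,
                                       config$length_jitter_s)
      n <- fft_friendly_length(round(actual_s * fs))
      # nominal phase time of each sample, and its session time (the kept
      # window of the final rest is centered in the recording)
      tn <- seq(0, rec_s, length.out = n)
      kept_start <- (rec_s - ph$nominal_s) / 2
      t_sess <- onsets[[ph$name]] + (tn - kept_start)
      s_norm <- (pmin(5, pmax(1, traj_fun(pmin(total_s, pmax(0, t_sess))))) - 1) / 4

      dat <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
      for (b in seq_len(nrow(bands))) {
        base <- config$band_baseline_uv2[[bands$name[b]]]
        cpl <- config$coupling[[bands$name[b]]]
        gain <- sqrt(base * (1 + cpl * s_norm))
        for (ch in channels) {
          g <- gain
          if (bands$name[b] == "Alpha" && ch == "F6")
            g <- g * sqrt(config$alpha_asym_ratio)
          dat[, ch] <- dat[, ch] +
            g * band_noise(n, fs, bands$low_hz[b], bands$high_hz[b])
        }
      }
      if (config$line_amp_uv > 0) {
        tt <- (seq_len(n) - 1) / fs
        for (ch in channels)
          dat[, ch] <- dat[, ch] +
            config$line_amp_uv * sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
      }
      if (config$artifact_prob > 0) {
        hit <- which(stats::runif(counts[[ph$name]]) < config$artifact_prob)
        burst <- artifact_burst(fs, amp = config$artifact_uv)
        for (k in hit) {
          centre_tn <- kept_start + (k - 0.5) * schedule$epoch_s
          c0 <- round(centre_tn / rec_s * (n - 1)) + 1
          idx <- c0 - floor(length(burst) / 2) + seq_along(burst) - 1
          keep <- idx >= 1 & idx <= n
          ch <- sample(channels, 1)
          dat[idx[keep], ch] <- dat[idx[keep], ch] + burst[keep]
        }
        artifact_epochs <- c(artifact_epochs, epoch_offset + hit - 1L)
      }
      epoch_offset <- epoch_offset + counts[[ph$name]]
      recordings[[ph$name]] <- eeg_recording(dat, fs = fs, phase = ph$name,
                                             nominal_s = ph$recorded_s)
    }

    list(recordings = recordings,
         truth = list(trajectory = trajectory, surveys = surveys,
                      artifact_epochs = as.integer(artifact_epochs),
                      anchors = anchors))
  })
}
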