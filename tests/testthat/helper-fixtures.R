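# Shared fixtures built in code. Sessions are cached per options() key so the
# expensive simulate/preprocess work runs once per test session.

fixture_env <- new.env(parent = emptyenv())

# A quiet, artifact-free, jitter-free synthetic config for tests that need a
# clean signal path.
clean_config <- function(seed = 1, ...) {
  synth_config(seed = seed, line_amp_uv = 0, artifact_prob = 0,
               survey_jitter_prob = 0, length_jitter_s = 0, ...)
}

# Strong feature-stress coupling, low reporting noise: the regime in which a
# regressor should recover the stress trajectory.
strong_coupling <- function(seed = 1) {
  synth_config(seed = seed,
               coupling = c(Delta = 0, Theta = -0.3, Alpha = -0.5,
                            Beta = 1, Gamma = 2),
               survey_jitter_prob = 0)
}

cached_session <- function(key, config_fn = synth_config, seed = 1) {
  if (is.null(fixture_env[[key]])) {
    sched <- build_default_schedule()
    sess <- simulate_session(sched, config_fn(seed = seed))
    eps <- preprocess_session(sess$recordings, sched)
    fm <- extract_features(eps)
    fixture_env[[key]] <- list(schedule = sched, session = sess,
                               epochs = eps, features = fm)
  }
  fixture_env[[key]]
}

default_session <- function() cached_session("default", synth_config, seed = 1)
clean_session <- function() cached_session("clean", clean_config, seed = 1)

# Minimal single-channel-set recording from a generator function of time.
probe_recording <- function(f, dur_s = 10, fs = 256, phase = "probe",
                            channels = c("Fp1", "Fp2", "F5", "F6")) {
  t <- (seq_len(round(dur_s * fs)) - 1) / fs
  x <- f(t)
  dat <- matrix(rep(x, length(channels)), ncol = length(channels),
                dimnames = list(NULL, channels))
  eeg_recording(dat, fs = fs, phase = phase, nominal_s = dur_s)
}

rms <- function(x) sqrt(mean(x^2))

# Interior of a filtered probe, clear of filter edge transients.
interior <- function(x, trim = 512) x[(trim + 1):(length(x) - trim)]

# Build an epoch_array directly from an epochs x channels x samples array.
manual_epochs <- function(arr, fs = 256,
                          channels = c("Fp1", "Fp2", "F5", "F6"),
                          phase = "manual") {
  structure(
    list(epochs = arr, mask = rep(FALSE, dim(arr)[1]), channels = channels,
         phase = phase, fs = fs, epoch_s = dim(arr)[3] / fs),
    class = "epoch_array"
  )
}

# Default 8-survey series with the given answers on the default knot times.
make_surveys <- function(spsl) {
  survey_series(data.frame(
    survey_id = paste0("T", 1:8),
    time_s = c(0, 120, 240, 360, 450, 540, 660, 720),
    spsl = spsl
  ))
}
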