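# Independent PSD oracle: direct DFT of the windowed epoch plus trapezoidal
# integration, written without the package's periodogram helpers.
oracle_band_power <- function(x, fs, lo, hi, alpha = 0.25) {
  n <- length(x)
  w <- stresseeg::tukey_window(n, alpha)
  xw <- x * w
  k <- 0:(n %/% 2)
  X <- vapply(k, function(kk)
    abs(sum(xw * exp(-2i * pi * kk * (0:(n - 1)) / n))), numeric(1))
  psd <- 2 * X^2 / (fs * sum(w^2))
  psd[1] <- psd[1] / 2
  if (n %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  f <- k * fs / n
  sel <- which(f >= lo & f < hi)
  sum(diff(f[sel]) * (psd[sel[-length(sel)]] + psd[sel[-1]]) / 2)
}

tone_epochs <- function(freq, n_ep = 1, amp = sqrt(2), fs = 256, spe = 512) {
  t <- (0:(spe - 1)) / fs
  x <- amp * sin(2 * pi * freq * t)
  arr <- array(rep(x, each = n_ep * 4), c(n_ep, 4, spe))
  manual_epochs(arr, fs = fs)
}

test_that("band table is the canonical ascending partition", {
  b <- eeg_bands()
  expect_equal(b$name, c("Delta", "Theta", "Alpha", "Beta", "Gamma"))
  expect_true(all(b$low_hz < b$high_hz))
  expect_true(all(diff(b$low_hz) > 0))
  expect_equal(b$low_hz[-1], b$high_hz[-nrow(b)])  # contiguous 1-45 Hz
})

test_that("all-zero epochs yield zero band powers and a zero feature row", {
  ep <- manual_epochs(array(0, c(3, 4, 512)))
  bp <- epoch_band_powers(ep)
  expect_true(all(bp == 0))
  fm <- assemble_features(bp)
  expect_equal(unname(fm$values[1, ]), rep(0, 7))
})

test_that("a 10 Hz tone lands in the Alpha band", {
  bp <- epoch_band_powers(tone_epochs(10))
  alpha <- bp[1, 1, "Alpha"]
  others <- bp[1, 1, setdiff(dimnames(bp)[[3]], "Alpha")]
  expect_true(all(alpha > 10 * others))
})

test_that("band power of a pure tone matches the direct-DFT oracle within 1%", {
  for (freq in c(6, 10.25, 30)) {
    ep <- tone_epochs(freq)
    bp <- epoch_band_powers(ep)
    b <- eeg_bands()
    bi <- which(b$low_hz <= freq & freq < b$high_hz)
    want <- oracle_band_power(ep$epochs[1, 1, ], 256, b$low_hz[bi], b$high_hz[bi])
    expect_equal(unname(bp[1, 1, bi]), want, tolerance = 0.01)
  }
})

test_that("white-noise band power is roughly proportional to bandwidth", {
  arr <- with_seed(42, array(rnorm(100 * 4 * 512), c(100, 4, 512)))
  bp <- epoch_band_powers(manual_epochs(arr))
  avg <- apply(bp, 3, mean)
  b <- eeg_bands()
  dens <- avg / (b$high_hz - b$low_hz)  # power per Hz, should be flat
  expect_true(all(abs(dens / mean(dens) - 1) < 0.25))
})

test_that("relative gamma follows its defining ratio", {
  expect_equal(relative_gamma(1, 1, 1), 0.5)
  expect_equal(relative_gamma(0, 2, 3), 0)
  expect_equal(relative_gamma(2, 3, 1), 0.5)
  expect_equal(relative_gamma(3, 0, 0), 0)  # zeroed epoch convention
  expect_error(relative_gamma(-1, 1, 1))
})

test_that("alpha asymmetry is the signed F6 minus F5 difference", {
  expect_equal(alpha_asymmetry(2, 2), 0)
  expect_equal(alpha_asymmetry(3, 1), 2)
  expect_equal(alpha_asymmetry(1, 3), -2)
})

test_that("a right-dominant alpha gain gives positive asymmetry in most epochs", {
  sched <- build_default_schedule()
  cfg <- clean_config(seed = 5, alpha_asym_ratio = 2)
  sess <- simulate_session(sched, cfg)
  fm <- extract_features(preprocess_session(sess$recordings, sched))
  expect_gt(mean(fm$values[!fm$mask, "AA"] > 0), 0.9)
})

test_that("assembly averages channels and keeps the 7-column contract", {
  arr <- with_seed(9, array(rep(rnorm(512 * 5), each = 1), c(5, 1, 512)))
  arr4 <- array(arr[, rep(1, 4), ], c(5, 4, 512))  # identical channels
  bp <- epoch_band_powers(manual_epochs(arr4))
  fm <- assemble_features(bp)
  expect_equal(colnames(fm$values),
               c("P_Delta", "P_Theta", "P_Alpha", "P_Beta", "P_Gamma",
                 "RG", "AA"))
  expect_equal(unname(fm$values[, "P_Alpha"]), unname(bp[, 1, "Alpha"]))
  expect_equal(unname(fm$values[, "AA"]), rep(0, 5))

  bad <- bp
  dimnames(bad)[[2]] <- c("Fp1", "Fp2", "C3", "C4")
  expect_error(assemble_features(bad), "F5")
})

test_that("the session feature matrix is 360 x 7", {
  fm <- default_session()$features
  expect_equal(dim(fm$values), c(360, 7))
  expect_true(all(fm$values[, 1:6] >= 0))  # band powers and RG non-negative
})

test_that("scaling a signal by c scales powers by c^2 and leaves RG fixed", {
  arr <- with_seed(11, array(rnorm(4 * 4 * 512), c(4, 4, 512)))
  bp1 <- epoch_band_powers(manual_epochs(arr))
  bp3 <- epoch_band_powers(manual_epochs(3 * arr))
  expect_equal(bp3, 9 * bp1, tolerance = 1e-12)
  f1 <- assemble_features(bp1)$values
  f3 <- assemble_features(bp3)$values
  expect_equal(f3[, "RG"], f1[, "RG"], tolerance = 1e-12)
  expect_equal(sign(f3[, "AA"]), sign(f1[, "AA"]))
})

test_that("feature smoothing matches a direct truncated-window oracle", {
  n <- 180
  vals <- matrix(0, n, 7, dimnames = list(NULL, feature_names <-
    c("P_Delta", "P_Theta", "P_Alpha", "P_Beta", "P_Gamma", "RG", "AA")))
  vals[51, ] <- 1  # unit impulse at 0-based epoch 50
  fm <- structure(list(values = vals, phase = rep("mist_test", n),
                       epoch_start_s = (0:(n - 1)) * 2),
                  class = "feature_matrix")
  sm <- smooth_features(fm, window_s = 30)
  oracle <- vapply(seq_len(n), function(i) {
    w <- max(1, i - 7):min(n, i + 7)
    mean(vals[w, 1])
  }, numeric(1))
  expect_equal(unname(sm$values[, 1]), oracle)
  expect_equal(unname(sm$values[44:58, 1]), rep(1 / 15, 15))
  expect_true(all(sm$values[c(1:43, 59:n), 1] == 0))
})

test_that("smoothing keeps constants, degenerates to identity, and conserves interior mass", {
  n <- 60
  vals <- matrix(3, n, 7)
  colnames(vals) <- c("P_Delta", "P_Theta", "P_Alpha", "P_Beta", "P_Gamma",
                      "RG", "AA")
  fm <- structure(list(values = vals, phase = rep("relax", n),
                       epoch_start_s = (0:(n - 1)) * 2),
                  class = "feature_matrix")
  expect_equal(smooth_features(fm, window_s = 30)$values, vals)
  expect_equal(smooth_features(fm, window_s = 2)$values, vals)
  expect_error(smooth_features(fm, window_s = 0.5), "at least one epoch")

  vals2 <- vals
  vals2[, 1] <- 0
  vals2[25:35, 1] <- with_seed(2, runif(11))
  fm2 <- structure(list(values = vals2, phase = rep("relax", n),
                        epoch_start_s = (0:(n - 1)) * 2),
                   class = "feature_matrix")
  sm2 <- smooth_features(fm2, window_s = 30)
  expect_equal(mean(sm2$values[, 1]), mean(vals2[, 1]), tolerance = 1e-9)
})

test_that("smoothing is confined to each phase recording", {
  vals <- matrix(0, 20, 7)
  colnames(vals) <- c("P_Delta", "P_Theta", "P_Alpha", "P_Beta", "P_Gamma",
                      "RG", "AA")
  vals[10, ] <- 1  # last epoch of phase A
  fm <- structure(list(values = vals,
                       phase = rep(c("A", "B"), each = 10),
                       epoch_start_s = c(0:9, 0:9) * 2),
                  class = "feature_matrix")
  sm <- smooth_features(fm, window_s = 30)
  expect_true(all(sm$values[11:20, 1] == 0))  # no bleed into phase B
  expect_gt(sm$values[10, 1], 0)
})

test_that("feature matrices round-trip through the delimited format", {
  fm <- default_session()$features
  path <- file.path(tempdir(), "fm.csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$values, fm$values, tolerance = 1e-6)
  expect_equal(back$phase, fm$phase)
  file.remove(path)
})
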