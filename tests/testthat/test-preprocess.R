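test_that("notch filter suppresses 50 Hz and passes 10 Hz", {
  r50 <- probe_recording(function(t) 10 * sin(2 * pi * 50 * t))
  r10 <- probe_recording(function(t) 10 * sin(2 * pi * 10 * t))
  y50 <- notch_filter(r50)$data[, 1]
  y10 <- notch_filter(r10)$data[, 1]
  expect_lt(rms(interior(y50)) / rms(interior(r50$data[, 1])), 0.10)
  ratio10 <- rms(interior(y10)) / rms(interior(r10$data[, 1]))
  expect_lt(abs(ratio10 - 1), 0.05)
  # >= 20 dB attenuation at the mains frequency
  att_db <- 20 * log10(rms(interior(y50)) / rms(interior(r50$data[, 1])))
  expect_lt(att_db, -20)

  rz <- probe_recording(function(t) 0 * t)
  expect_equal(max(abs(notch_filter(rz)$data)), 0)
  rbad <- probe_recording(function(t) 0 * t)
  rbad$data[5, 2] <- NaN
  expect_error(notch_filter(rbad), "finite")
})

test_that("bandpass filter removes drift and high frequencies with zero phase", {
  rdrift <- probe_recording(function(t) sin(2 * pi * 0.2 * t), dur_s = 30)
  r60 <- probe_recording(function(t) sin(2 * pi * 60 * t))
  r10 <- probe_recording(function(t) sin(2 * pi * 10 * t))
  expect_lt(rms(interior(bandpass_filter(rdrift)$data[, 1], 1024)) /
              rms(interior(rdrift$data[, 1], 1024)), 0.10)
  y60 <- bandpass_filter(r60)$data[, 1]
  expect_lt(rms(interior(y60)) / rms(interior(r60$data[, 1])), 0.10)
  expect_lt(20 * log10(rms(interior(y60)) / rms(interior(r60$data[, 1]))), -20)
  # zero phase: cross-correlation of a 10 Hz probe peaks at lag 0
  y10 <- interior(bandpass_filter(r10)$data[, 1])
  x10 <- interior(r10$data[, 1])
  cc <- ccf(y10, x10, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("resampling hits the exact nominal sample count and preserves band power", {
  f <- function(t) sin(2 * pi * 10 * t)
  r363 <- probe_recording(f, dur_s = 363)
  r363$nominal_s <- 360
  out <- resample_to_nominal(r363)
  expect_equal(nrow(out$data), 360 * 256)

  r300 <- probe_recording(f, dur_s = 303)
  r300$nominal_s <- 300
  expect_equal(nrow(resample_to_nominal(r300)$data), 300 * 256)

  rsame <- probe_recording(f, dur_s = 60)
  same <- resample_to_nominal(rsame)
  expect_equal(nrow(same$data), 60 * 256)
  expect_equal(same$data, rsame$data, tolerance = 1e-9)

  # band power of an in-band probe changes by < 2%
  p_in <- mean(interior(r363$data[, 1])^2)
  p_out <- mean(interior(out$data[, 1])^2)
  expect_lt(abs(p_out - p_in) / p_in, 0.02)

  rbad <- probe_recording(f, dur_s = 100)
  rbad$nominal_s <- 300
  expect_error(resample_to_nominal(rbad), "corrupt")
})

test_that("central-minute extraction returns the centered 60-s window", {
  f <- function(t) t  # ramp encodes sample position
  r120 <- probe_recording(f, dur_s = 120)
  out <- extract_central_minute(r120)
  expect_equal(nrow(out$data), 60 * 256)
  expect_equal(unname(out$data[1, 1]), 30, tolerance = 1e-9)
  expect_equal(out$nominal_s, 60)

  r60 <- probe_recording(f, dur_s = 60)
  expect_equal(extract_central_minute(r60)$data, r60$data)

  r100 <- probe_recording(f, dur_s = 100)
  expect_equal(unname(extract_central_minute(r100)$data[1, 1]), 20,
               tolerance = 1e-9)

  expect_error(extract_central_minute(probe_recording(f, dur_s = 30)),
               "shorter")
})

test_that("epoching yields the protocol epoch counts", {
  eps <- default_session()$epochs
  expect_equal(vapply(eps, function(e) dim(e$epochs)[1], numeric(1)),
               c(mist_test = 180, relax = 150, rest2 = 30))
  expect_equal(sum(vapply(eps, function(e) dim(e$epochs)[1], numeric(1))), 360)
  for (e in eps) expect_equal(dim(e$epochs)[3], 512)

  rodd <- probe_recording(function(t) t, dur_s = 3)  # not a multiple of 2 s
  expect_error(epoch_recording(rodd), "multiple")
})

test_that("outlier zeroing masks exactly the epochs above threshold", {
  arr <- array(rnorm(10 * 4 * 512, sd = 5), c(10, 4, 512))
  arr[4, 3, 100] <- 80  # one sample at +80 uV on F5
  ep <- manual_epochs(arr)
  out <- zero_outlier_epochs(ep, 75)
  expect_equal(which(out$mask), 4)
  expect_true(all(out$epochs[4, , ] == 0))
  expect_equal(out$epochs[-4, , ], arr[-4, , ])

  quiet <- manual_epochs(array(rnorm(10 * 4 * 512, sd = 5), c(10, 4, 512)))
  out2 <- zero_outlier_epochs(quiet, 75)
  expect_false(any(out2$mask))
  expect_equal(out2$epochs, quiet$epochs)
})

test_that("injected artifacts are recovered exactly by the outlier stage", {
  fx <- default_session()
  masked <- which(unlist(lapply(fx$epochs, function(e) e$mask))) - 1L
  expect_equal(unname(masked), fx$session$truth$artifact_epochs)
})

test_that("artifact-free sessions yield an all-false mask", {
  fx <- clean_session()
  expect_false(any(unlist(lapply(fx$epochs, function(e) e$mask))))
})

test_that("mask size is monotone non-increasing in the threshold", {
  fx <- default_session()
  sess <- fx$session; sched <- fx$schedule
  counts <- vapply(c(40, 75, 120, 200), function(th) {
    eps <- preprocess_session(sess$recordings, sched, threshold_uv = th)
    sum(vapply(eps, function(e) sum(e$mask), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detrending and standardization normalize every live epoch", {
  arr <- array(rnorm(6 * 4 * 512, sd = 5), c(6, 4, 512))
  arr[2, , ] <- arr[2, , ] + outer(rep(1, 4), seq(0, 30, length.out = 512))
  ep <- detrend_standardize(zero_outlier_epochs(manual_epochs(arr), 75))
  for (i in which(!ep$mask)) for (ch in 1:4) {
    expect_lt(abs(mean(ep$epochs[i, ch, ])), 1e-9)
    expect_lt(abs(sd(ep$epochs[i, ch, ]) - 1), 1e-9)
  }
})

test_that("a pure linear ramp epoch is degenerate and gets masked", {
  arr <- array(rnorm(4 * 4 * 512), c(4, 4, 512))
  arr[3, , ] <- outer(rep(1, 4), 2 * seq_len(512) + 5)
  out <- detrend_standardize(manual_epochs(arr))
  expect_true(out$mask[3])
  expect_true(all(out$epochs[3, , ] == 0))
  expect_false(any(out$mask[-3]))
})

test_that("masked epochs pass through standardization untouched", {
  arr <- array(rnorm(5 * 4 * 512, sd = 40), c(5, 4, 512))
  arr[1, 2, 10] <- 100
  out <- detrend_standardize(zero_outlier_epochs(manual_epochs(arr), 75))
  expect_true(out$mask[1])
  expect_true(all(out$epochs[1, , ] == 0))
})

test_that("standardization is idempotent", {
  fx <- default_session()
  ep <- fx$epochs$rest2
  twice <- detrend_standardize(ep)
  expect_equal(twice$epochs, ep$epochs, tolerance = 1e-9)
  expect_equal(twice$mask, ep$mask)
})

test_that("the chained preprocessor equals the explicit stage sequence", {
  rec <- clean_session()$session$recordings$mist_test
  manual <- detrend_standardize(zero_outlier_epochs(epoch_recording(
    resample_to_nominal(bandpass_filter(notch_filter(rec)))), 75))
  auto <- preprocess_recording(rec, processed_s = 360)
  expect_identical(auto$epochs, manual$epochs)
  expect_identical(auto$mask, manual$mask)
})
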