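makeRec <- function(x, rate = 256, channels = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(x)))
  EEGRecording(x, channels, rate, "s01", "HC")
}

test_that("band-pass filter passes the passband and rejects outside it", {
  t <- (0:2559) / 256
  pass <- makeRec(sin(2 * pi * 10 * t))           # 10 Hz: inside 0.5-45
  out <- bandpassFilter(pass, 0.5, 45, 2)
  rms <- function(r) sqrt(mean(signalData(r)^2))
  expect_equal(rms(out) / rms(pass), 1, tolerance = 0.05)
  stopband <- makeRec(sin(2 * pi * 60 * t))       # 60 Hz: outside
  out60 <- bandpassFilter(stopband, 0.5, 45, 2)
  expect_lt(rms(out60) / rms(stopband), 0.5)
  # zeros in, zeros out
  z <- bandpassFilter(makeRec(rep(0, 2560)))
  expect_equal(max(abs(signalData(z))), 0)
})

test_that("filtering is idempotent in the passband", {
  t <- (0:2559) / 256
  rec <- makeRec(sin(2 * pi * 10 * t))
  once <- bandpassFilter(rec)
  twice <- bandpassFilter(once)
  rms <- function(r) sqrt(mean(signalData(r)^2))
  expect_equal(rms(twice) / rms(once), 1, tolerance = 0.01)
})

test_that("filter rejects invalid bands and too-short signals", {
  t <- (0:2559) / 256
  rec <- makeRec(sin(2 * pi * 10 * t))
  expect_error(bandpassFilter(rec, 0.5, 130), "Nyquist")
  expect_error(bandpassFilter(makeRec(rnorm(500))), "too short")
})

test_that("resampling hits the exact output length", {
  rec <- makeRec(rnorm(225000), rate = 250)
  out <- resampleRecording(rec, 256)
  expect_identical(nSamples(out), 230400L)        # n * 256/250
  expect_equal(sampleRate(out), 256)
  rec2 <- makeRec(rnorm(1024), rate = 1024)
  expect_identical(nSamples(resampleRecording(rec2, 256)), 256L)
  # identity rate: untouched
  rec3 <- makeRec(rnorm(1000), rate = 256)
  out3 <- resampleRecording(rec3, 256)
  expect_lt(max(abs(signalData(out3) - signalData(rec3))), 1e-9)
  expect_error(resampleRecording(rec3, -1), "targetHz")
})

test_that("resampling preserves in-band content", {
  t <- (0:24999) / 250
  rec <- makeRec(sin(2 * pi * 10 * t), rate = 250)
  out <- resampleRecording(rec, 256)
  t2 <- (seq_len(nSamples(out)) - 1) / 256
  ref <- sin(2 * pi * 10 * t2)
  core <- 500:25000                                # ignore edge taper
  expect_gt(cor(signalData(out)[1, core], ref[core]), 0.999)
})

test_that("segmentation yields floor(duration/length) labelled windows", {
  rec <- makeRec(matrix(rnorm(2 * 900 * 256), 2), rate = 256)
  segs <- segmentRecording(rec, 3)
  expect_length(segs, 300)
  expect_true(all(vapply(segs, function(s) ncol(signalData(s)), 0L) == 768L))
  segs7 <- segmentRecording(makeRec(rnorm(7 * 256)), 3)
  expect_length(segs7, 2)                          # final second dropped
  expect_identical(vapply(segs7, function(s) s@segmentIndex, 0L), c(0L, 1L))
  expect_true(all(vapply(segs7, classLabel, "") == "HC"))
  expect_warning(segmentRecording(makeRec(rnorm(100)), 3), "shorter")
})

test_that("concatenated segments reproduce the source samples exactly", {
  rec <- makeRec(matrix(rnorm(2 * 2000), 2), rate = 256)
  segs <- segmentRecording(rec, 3)
  recon <- do.call(cbind, lapply(segs, signalData))
  expect_identical(recon, signalData(rec)[, seq_len(ncol(recon))])
})

test_that("the preprocessing chain composes filter, resample, segment", {
  rec <- makeRec(matrix(rnorm(2 * 15000), 2), rate = 250)
  segs <- preprocessRecording(rec)
  expect_length(segs, 20)                          # 60 s -> 20 windows
  expect_equal(sampleRate(segs[[1]]), 256)
  expect_identical(ncol(signalData(segs[[1]])), 768L)
  # sub-band override uses the named band edges
  expect_error(preprocessRecording(rec, band = "sigma"), "unknown band")
  alpha <- preprocessRecording(rec, band = "alpha")
  spectrumPeak <- function(seg) {
    x <- signalData(seg)[1, ]
    f <- pmin(0:767, 768 - (0:767)) * 256 / 768
    f[which.max(Mod(stats::fft(x))^2 * (f > 0 & f <= 128))]
  }
  expect_true(all(vapply(alpha[1:5], spectrumPeak, 0) >= 6))
})
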