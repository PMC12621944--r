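test_that("the mel scale matches its closed form and is monotone", {
  expect_identical(melScale(0), 0)
  expect_equal(melScale(700), 2595 * log10(2), tolerance = 1e-9)
  expect_true(melScale(45) > melScale(12.5) && melScale(12.5) > melScale(4))
  expect_equal(melToHz(melScale(c(0.5, 10, 45))), c(0.5, 10, 45),
               tolerance = 1e-9)
  expect_error(melScale(-1), "non-negative")
})

test_that("the STFT places energy at the right bin and time", {
  # zeros in, zeros out
  z <- computeSTFT(rep(0, 768), stftParams(), 256)
  expect_equal(max(Mod(z)), 0)
  expect_identical(dim(z), c(17L, 129L))
  # 10 Hz sine at 256 Hz with nFft 256: argmax at bin 10 (index 11)
  x <- sin(2 * pi * 10 * (0:767) / 256)
  S <- computeSTFT(x, stftParams(), 256)
  peaks <- apply(Mod(S), 1, which.max)
  expect_true(all(peaks == 11))
  expect_error(computeSTFT(rnorm(100), stftParams(nFft = 256)), "window")
})

test_that("one frame of the STFT satisfies Parseval's identity", {
  set.seed(4)
  x <- rnorm(256)
  S <- computeSTFT(x, stftParams(nFft = 256, hop = 256), 256)
  expect_identical(nrow(S), 1L)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:255) / 255)
  timeEnergy <- sum((w * x)^2)
  mag2 <- Mod(S[1, ])^2
  freqEnergy <- (mag2[1] + mag2[129] + 2 * sum(mag2[2:128])) / 256
  expect_equal(freqEnergy, timeEnergy, tolerance = 1e-9)
})

test_that("mel filters are unimodal, overlapping and mel-equispaced", {
  fb <- melFilterbank(melParams(), 256, 256)
  expect_identical(dim(fb), c(64L, 129L))
  expect_true(all(fb >= 0))
  for (m in seq_len(nrow(fb))) {
    row <- fb[m, ]
    peak <- which.max(row)
    expect_true(all(diff(row[seq_len(peak)]) >= -1e-12))
    expect_true(all(diff(row[peak:length(row)]) <= 1e-12))
  }
  # adjacent triangles overlap: filter k's upper edge lies above filter
  # k+1's lower edge for every neighbouring pair
  edges <- attr(fb, "edgesHz")
  for (m in seq_len(nrow(fb) - 1))
    expect_gt(edges[m + 2], edges[m + 1])  # (lo_k, ctr_k, hi_k) = edges[m..m+2]
  # centres equally spaced on the mel axis to within half a bin
  ctr <- attr(fb, "centerHz")
  melCtr <- melScale(ctr)
  spacing <- diff(melCtr)
  binMel <- diff(melScale(c(0, 1)))  # one FFT bin (1 Hz) near DC, in mels
  expect_lt(max(abs(spacing - mean(spacing))), binMel / 2)
  # support confined to [fMin, fMax]
  binHz <- (0:128) * 256 / 256
  expect_true(all(binHz[which(colSums(fb) > 0)] > 0.5 - 1e-9))
  expect_true(all(binHz[which(colSums(fb) > 0)] < 45 + 1e-9))
  # a flat power spectrum excites every mel bin
  expect_true(all(fb %*% rep(1, 129) > 0))
  # unresolvable request errors out
  expect_error(melFilterbank(melParams(nMels = 200), 64, 256), "empty mel")
})

test_that("rendered images satisfy the shape/range contract", {
  set.seed(7)
  seg <- makeSegment(matrix(rnorm(2 * 768), 2), c("O1", "O2"))
  img <- segmentToImage(seg)
  px <- imagePixels(img)
  expect_identical(dim(px), c(224L, 224L, 3L))
  expect_true(is.integer(px))
  expect_gte(min(px), 0L)
  expect_lte(max(px), 255L)
})

test_that("an all-zero segment renders as a constant mid-level image", {
  seg <- makeSegment(matrix(0, 2, 768), c("O1", "O2"))
  img <- segmentToImage(seg, colormap = "gray")
  px <- imagePixels(img)
  expect_identical(length(unique(as.vector(px))), 1L)
  expect_identical(px[1, 1, 1], 128L)
})

test_that("a localized burst lights up the right time and frequency", {
  x <- rep(0, 768)
  x[257:512] <- 10 * sin(2 * pi * 10 * (0:255) / 256)  # middle second
  seg <- makeSegment(matrix(x, 1), "Cz")
  img <- segmentToImage(seg, size = 224, colormap = "gray")
  px <- imagePixels(img)[, , 1]
  bright <- which(px == max(px), arr.ind = TRUE)
  xPos <- mean(bright[, 2]); yPos <- mean(bright[, 1])
  expect_gt(xPos, 224 / 3)                 # middle third of the time axis
  expect_lt(xPos, 2 * 224 / 3)
  ctr <- attr(melFilterbank(melParams(), 256, 256), "centerHz")
  k <- which.min(abs(ctr - 10))
  yExpect <- 224 * (1 - (k - 0.5) / 64)    # low frequencies at the bottom
  expect_lt(abs(yPos - yExpect), 2 / 64 * 224)  # within +/- 2 mel bins
})

test_that("channel order and global amplitude do not change the image", {
  set.seed(9)
  data <- matrix(rnorm(3 * 768), 3)
  seg <- makeSegment(data, c("Fp1", "Cz", "O1"))
  perm <- makeSegment(data[c(3, 1, 2), ], c("O1", "Fp1", "Cz"))
  expect_identical(imagePixels(segmentToImage(seg)),
                   imagePixels(segmentToImage(perm)))
  scaled <- makeSegment(10 * data, c("Fp1", "Cz", "O1"))
  expect_identical(imagePixels(segmentToImage(seg)),
                   imagePixels(segmentToImage(scaled)))
})
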