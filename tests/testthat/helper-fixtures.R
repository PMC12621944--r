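# Shared fixtures, all generated in code.

# 64-channel task-montage labels (10-20 extended system) used to exercise
# the 64 -> 19 channel selection.
kaggle64Names <- c(
  "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
  "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
  "FT7", "T7", "TP7", "FT8", "T8", "TP8",
  "P7", "P8", "P9", "P10",
  "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
  "P5", "P3", "P1", "Pz", "P2", "P4", "P6",
  "O1", "Oz", "O2", "Iz",
  "PO7", "PO3", "POz", "PO4", "PO8"
)

makeSegment <- function(data, channels = paste0("ch", seq_len(nrow(data))),
                        rate = 256, label = "HC", index = 0L) {
  new("EEGSegment", data = data, channelNames = channels, rateHz = rate,
      subjectId = "s01", label = label, segmentIndex = as.integer(index))
}

# Trivially separable planted-blob toy images: both classes carry a
# bright band strictly inside the top half (rows ~3..12 of 32), red for
# HC and blue for ScZ. The discriminative evidence is colour-coded at a
# fixed location, so the top half is the only informative region for
# both classes and each class has its own positively-coded detector -
# the regime channel-weighted activation maps are designed for.
toyImageSet <- function(n = 16, side = 32, seed = 1) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  band <- seq(max(1, round(side * 0.1)), round(side * 0.38))
  mk <- function(scz) {
    a <- array(40L, dim = c(side, side, 3))
    a[band, , if (scz) 3 else 1] <- 230L
    a + array(sample(0:10, side * side * 3, TRUE), dim = c(side, side, 3))
  }
  list(images = lapply(seq_len(n), function(i) mk(i > n / 2)),
       labels = rep(c("HC", "ScZ"), each = n / 2))
}

# Cache expensive fixtures across tests within one run.
.fixtureCache <- new.env(parent = emptyenv())

# Toy classifier trained on the bright-top / bright-bottom set.
toyClassifier <- function() {
  if (!is.null(.fixtureCache$toyModel)) return(.fixtureCache$toyModel)
  toy <- toyImageSet(16, 32)
  model <- buildModel(cnnConfig(inputSize = 32), seed = 1)
  model <- trainModel(model, toy$images, toy$labels, epochs = 30,
                      batchSize = 8, seed = 1)
  .fixtureCache$toyModel <- list(model = model, images = toy$images,
                                 labels = toy$labels)
  .fixtureCache$toyModel
}

# Structure-recovery cohort at the study conditions (8 subjects/class,
# 60 s, frontal alpha effect at SNR 0.8, fixed cohort seed), preprocessed
# once and rendered at 64x64 per requested region.
recoveryImages <- function(region) {
  key <- paste0("imgs_", region)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  if (is.null(.fixtureCache$recoveryPre)) {
    spec <- cohortSpec(nSubjectsPerClass = 8, durationS = 60,
                       effectSnr = 0.8, seed = 101)
    cohort <- generateCohort(spec)
    .fixtureCache$recoveryPre <- lapply(cohort, function(rec)
      resampleRecording(bandpassFilter(rec), 256))
  }
  tab <- lobeTable("repod19")
  segs <- unlist(lapply(.fixtureCache$recoveryPre, function(rec)
    segmentRecording(applyMontage(rec, tab, region), 3)),
    recursive = FALSE)
  imgs <- lapply(segs, segmentToImage, size = 64, region = region)
  out <- list(images = imgs,
              labels = vapply(imgs, function(im) im@label, ""),
              subjects = vapply(imgs, function(im) im@subjectId, ""))
  .fixtureCache[[key]] <- out
  out
}

# Independent periodogram-based spectral estimates (oracles).
periodogramSlope <- function(x, rateHz, fLow, fHigh) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * rateHz / n
  keep <- f >= fLow & f <= fHigh & seq_len(n) <= n / 2
  fit <- stats::lm(log(P[keep]) ~ log(f[keep]))
  unname(coef(fit)[2])
}

bandPowerFraction <- function(x, rateHz, bandHz) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * rateHz / n
  sum(P[f >= bandHz[1] & f <= bandHz[2]]) / sum(P[f > 0])
}
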