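#' @include AllClasses.R montage.R
NULL

#' Create an EEG recording object
#'
#' @param data numeric matrix, channels in rows and samples in columns.
#' @param channelNames character vector of channel labels, one per row.
#' @param rateHz sampling rate in Hz.
#' @param subjectId subject identifier.
#' @param label class label, `"HC"` or `"ScZ"`.
#' @return an [EEGRecording-class].
#' @examples
#' EEGRecording(matrix(rnorm(500), 2), c("C3", "C4"), 250, "s01", "HC")
#' @export
EEGRecording <- function(data, channelNames, rateHz, subjectId, label) {
  new("EEGRecording", data = as.matrix(data),
      channelNames = as.character(channelNames),
      rateHz = as.numeric(rateHz), subjectId = as.character(subjectId),
      label = as.character(label))
}

#' Specify a synthetic EEG cohort
#'
#' Builds a validated [CohortSpec-class]. The defaults emulate a balanced
#' 28-subject resting-state cohort: 14 subjects per class, 15-minute
#' recordings at 250 Hz on the 19-channel `"repod19"` montage, a pink
#' (1/f) background, and an alpha-band (8--12.5 Hz) class effect planted
#' into the frontal lobe of the ScZ recordings at an amplitude of 0.8
#' times the background RMS.
#'
#' @param nSubjectsPerClass subjects per class. Default 14.
#' @param durationS seconds of signal per subject. Default 900.
#' @param sourceRateHz source sampling rate in Hz. Default 250.
#' @param channelSet `"repod19"` or `"kaggle19"`.
#' @param effectLobes lobe names that receive the class effect.
#' @param effectBandHz length-2 numeric (low, high) in Hz.
#' @param effectSnr planted-oscillation RMS relative to background RMS.
#' @param noiseExponent spectral slope alpha of the 1/f^alpha background.
#' @param seed master seed.
#' @return a [CohortSpec-class].
#' @seealso [generateCohort()]
#' @export
cohortSpec <- function(nSubjectsPerClass = 14L, durationS = 900,
                       sourceRateHz = 250, channelSet = "repod19",
                       effectLobes = "frontal",
                       effectBandHz = c(8, 12.5), effectSnr = 0.8,
                       noiseExponent = 1, seed = 1L) {
  new("CohortSpec",
      nSubjectsPerClass = as.integer(nSubjectsPerClass),
      durationS = as.numeric(durationS),
      sourceRateHz = as.numeric(sourceRateHz),
      channelSet = as.character(channelSet),
      effectLobes = as.character(effectLobes),
      effectBandHz = as.numeric(effectBandHz),
      effectSnr = as.numeric(effectSnr),
      noiseExponent = as.numeric(noiseExponent),
      seed = as.integer(seed))
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pink (1/f^alpha) noise
#'
#' Generates a zero-mean, unit-RMS stochastic signal whose power spectral
#' density is proportional to 1/f^alpha in expectation, by spectrally
#' shaping Gaussian white noise (the DC component is removed).
#'
#' @param nSamples number of samples (>= 2).
#' @param alpha spectral slope in \[0, 2\]; 0 gives white noise, 1 the
#'   classical EEG-like pink background.
#' @param seed optional seed; the same (arguments, seed) pair always
#'   returns the identical vector.
#' @return numeric vector of length `nSamples`.
#' @examples
#' x <- pinkNoise(1024, alpha = 1, seed = 7)
#' round(mean(x), 12)  # 0
#' @export
pinkNoise <- function(nSamples, alpha = 1, seed = NULL) {
  if (length(nSamples) != 1L || !is.finite(nSamples) || nSamples < 2)
    stop("'nSamples' must be a single integer >= 2")
  if (alpha < 0 || alpha > 2)
    stop("'alpha' must lie in [0, 2]")
  nSamples <- as.integer(nSamples)
  .withSeed(seed, {
    w <- stats::rnorm(nSamples)
    W <- stats::fft(w)
    k <- 0:(nSamples - 1L)
    fr <- pmin(k, nSamples - k)      # symmetric bin frequencies
    H <- c(0, fr[-1]^(-alpha / 2))   # zero out DC -> zero mean
    x <- Re(stats::fft(W * H, inverse = TRUE)) / nSamples
    x <- x - mean(x)
    x / sqrt(mean(x^2))
  })
}

#' Band-limited stochastic oscillation
#'
#' A narrow-band noise signal confined to `bandHz` (brick-wall spectral
#' masking of Gaussian noise), scaled to an exact sample RMS. Used as the
#' planted class effect of the cohort simulator; its drifting phase and
#' amplitude give the downstream spectrogram texture that a deterministic
#' sinusoid would lack.
#'
#' @param nSamples number of samples (>= 2).
#' @param rateHz sampling rate in Hz.
#' @param bandHz length-2 numeric (low, high), inside (0, rateHz/2).
#' @param rms target sample RMS; 0 returns the all-zeros vector.
#' @param seed optional seed for reproducibility.
#' @return numeric vector of length `nSamples`.
#' @examples
#' x <- plantedOscillation(2560, 256, c(8, 12.5), rms = 2, seed = 1)
#' sqrt(mean(x^2))  # 2
#' @export
plantedOscillation <- function(nSamples, rateHz, bandHz, rms, seed = NULL) {
  if (length(nSamples) != 1L || !is.finite(nSamples) || nSamples < 2)
    stop("'nSamples' must be a single integer >= 2")
  if (length(bandHz) != 2L || bandHz[1] <= 0 || bandHz[2] <= bandHz[1] ||
      bandHz[2] >= rateHz / 2)
    stop("'bandHz' must satisfy 0 < low < high < rateHz/2")
  nSamples <- as.integer(nSamples)
  if (rms == 0) return(numeric(nSamples))
  .withSeed(seed, {
    w <- stats::rnorm(nSamples)
    W <- stats::fft(w)
    k <- 0:(nSamples - 1L)
    fr <- pmin(k, nSamples - k) * rateHz / nSamples
    keep <- fr >= bandHz[1] & fr <= bandHz[2]
    if (!any(keep))
      stop("'bandHz' is too narrow for the signal length: no spectral bins fall inside it")
    x <- Re(stats::fft(W * keep, inverse = TRUE)) / nSamples
    x <- x - mean(x)
    x * (rms / sqrt(mean(x^2)))
  })
}

# Deterministic per-subject sub-seed: a fixed linear congruential mix of the
# master seed and the subject index, stable across platforms and runs.
.subjectSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

#' Generate a synthetic EEG cohort
#'
#' Simulates one continuous recording per subject. Every channel carries
#' independent 1/f^alpha background noise (unit RMS, scaled to a nominal
#' 10 microvolt background); ScZ recordings additionally carry a shared
#' band-limited oscillation, with RMS `effectSnr` times the background
#' RMS, summed into exactly the channels of the effect lobes. HC
#' recordings carry no effect. Per-subject sub-seeds are derived
#' deterministically from the master seed, so the identical (spec, seed)
#' pair always reproduces the identical cohort bit for bit.
#'
#' @param spec a [CohortSpec-class].
#' @return list of [EEGRecording-class], HC subjects first.
#' @examples
#' spec <- cohortSpec(nSubjectsPerClass = 2, durationS = 10, seed = 7)
#' cohort <- generateCohort(spec)
#' vapply(cohort, classLabel, "")
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  tab <- lobeTable(spec@channelSet)
  channels <- fullChannels(tab)
  effectChannels <- toupper(unlist(lapply(spec@effectLobes,
                                          function(l) lobeChannels(tab, l))))
  n <- round(spec@durationS * spec@sourceRateHz)
  backgroundRms <- 10  # nominal microvolt scale
  makeSubject <- function(index, label, id) {
    .withSeed(.subjectSeed(spec@seed, index), {
      data <- matrix(0, nrow = length(channels), ncol = n)
      for (ch in seq_along(channels))
        data[ch, ] <- backgroundRms * pinkNoise(n, spec@noiseExponent)
      if (label == "ScZ" && spec@effectSnr > 0) {
        osc <- plantedOscillation(n, spec@sourceRateHz, spec@effectBandHz,
                                  rms = spec@effectSnr * backgroundRms)
        hit <- toupper(channels) %in% effectChannels
        data[hit, ] <- sweep(data[hit, , drop = FALSE], 2, osc, "+")
      }
      EEGRecording(data, channels, spec@sourceRateHz, id, label)
    })
  }
  nPer <- spec@nSubjectsPerClass
  c(
    lapply(seq_len(nPer), function(i)
      makeSubject(i, "HC", sprintf("HC%02d", i))),
    lapply(seq_len(nPer), function(i)
      makeSubject(nPer + i, "ScZ", sprintf("ScZ%02d", i)))
  )
}
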