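#' @include AllClasses.R
NULL

#' Physiological EEG frequency bands
#'
#' The sub-band edges used for optional per-band filtering: delta 2--4,
#' theta 4.5--7.5, alpha 8--12.5, beta 13--30 and gamma 30--45 Hz.
#'
#' @return named list of length-2 numeric vectors (low, high) in Hz.
#' @examples
#' eegBands()$alpha
#' @export
eegBands <- function() {
  list(delta = c(2, 4), theta = c(4.5, 7.5), alpha = c(8, 12.5),
       beta = c(13, 30), gamma = c(30, 45))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass
#' independently to every channel. The default 0.5--45 Hz order-2 filter is
#' the broadband cleaning step of the pipeline; passband gain is ~1 and the
#' forward-backward pass leaves no phase distortion to shift spectrogram
#' timing.
#'
#' @param recording an [EEGRecording-class].
#' @param lowHz lower corner frequency in Hz. Default 0.5.
#' @param highHz upper corner frequency in Hz. Default 45.
#' @param order Butterworth order of the underlying design. Default 2.
#' @return a filtered [EEGRecording-class] of the same shape.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 2560), 2), c("C3", "C4"),
#'                     256, "s01", "HC")
#' filt <- bandpassFilter(rec)
#' dim(signalData(filt))
#' @export
bandpassFilter <- function(recording, lowHz = 0.5, highHz = 45, order = 2L) {
  stopifnot(is(recording, "EEGRecording"))
  rate <- sampleRate(recording)
  if (!(0 < lowHz && lowHz < highHz))
    stop("need 0 < lowHz < highHz")
  if (highHz >= rate / 2)
    stop(sprintf("'highHz' (%g) must be below the Nyquist frequency (%g Hz)",
                 highHz, rate / 2))
  n <- nSamples(recording)
  settle <- ceiling(rate / lowHz)  # ~ one period of the slowest corner
  if (n <= 3 * settle)
    stop(sprintf(paste0("signal too short to filter: %d samples, need more ",
                        "than %d (3x the %g Hz corner's settling length)"),
                 n, 3 * settle, lowHz))
  bf <- signal::butter(order, c(lowHz, highHz) / (rate / 2), type = "pass")
  out <- recording@data
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- signal::filtfilt(bf, recording@data[ch, ])
  new("EEGRecording", data = out, channelNames = recording@channelNames,
      rateHz = rate, subjectId = recording@subjectId,
      label = recording@label)
}

# Integer rational approximation of a rate ratio.
.rateRatio <- function(targetHz, sourceHz) {
  scale <- 1000
  p <- round(targetHz * scale)
  q <- round(sourceHz * scale)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p = p / d, q = q / d)
}

#' Resample a recording to a target rate
#'
#' Per-channel polyphase (rational) resampling with anti-aliasing, via
#' [signal::resample()]. The output length is exactly
#' `round(nSamples * targetHz / sourceHz)`; when source and target rates
#' are equal the recording is returned unchanged.
#'
#' @param recording an [EEGRecording-class].
#' @param targetHz target sampling rate in Hz. Default 256.
#' @return an [EEGRecording-class] at `targetHz`.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 2500), 2), c("C3", "C4"),
#'                     250, "s01", "HC")
#' nSamples(resampleRecording(rec, 256))  # 2560
#' @export
resampleRecording <- function(recording, targetHz = 256) {
  stopifnot(is(recording, "EEGRecording"))
  if (length(targetHz) != 1L || !is.finite(targetHz) || targetHz <= 0)
    stop("'targetHz' must be a single positive rate")
  sourceHz <- sampleRate(recording)
  if (isTRUE(all.equal(targetHz, sourceHz))) return(recording)
  r <- .rateRatio(targetHz, sourceHz)
  nOut <- round(nSamples(recording) * targetHz / sourceHz)
  out <- matrix(0, nrow = nChannels(recording), ncol = nOut)
  for (ch in seq_len(nrow(out))) {
    y <- signal::resample(recording@data[ch, ], p = r["p"], q = r["q"])
    ny <- length(y)
    out[ch, ] <- if (ny >= nOut) y[seq_len(nOut)]
                 else c(y, rep(y[ny], nOut - ny))
  }
  new("EEGRecording", data = out, channelNames = recording@channelNames,
      rateHz = targetHz, subjectId = recording@subjectId,
      label = recording@label)
}

#' Cut a recording into fixed-length segments
#'
#' Non-overlapping consecutive windows of `round(lengthS * rateHz)`
#' samples. A trailing remainder shorter than one window is discarded; each
#' segment inherits the recording's label, channels and subject id and
#' carries a 0-based index.
#'
#' @param recording an [EEGRecording-class].
#' @param lengthS window length in seconds. Default 3.
#' @return list of [EEGSegment-class]; empty (with a warning) when the
#'   recording is shorter than one window.
#' @examples
#' rec <- EEGRecording(matrix(0, 1, 7 * 256), "Cz", 256, "s01", "HC")
#' length(segmentRecording(rec, 3))  # 2; final second dropped
#' @export
segmentRecording <- function(recording, lengthS = 3) {
  stopifnot(is(recording, "EEGRecording"))
  if (lengthS <= 0) stop("'lengthS' must be positive")
  win <- round(lengthS * sampleRate(recording))
  k <- nSamples(recording) %/% win
  if (k == 0L) {
    warning(sprintf("recording '%s' (%d samples) is shorter than one %g-s window; no segments",
                    subjectId(recording), nSamples(recording), lengthS))
    return(list())
  }
  lapply(seq_len(k) - 1L, function(i) {
    new("EEGSegment",
        data = recording@data[, (i * win + 1L):((i + 1L) * win), drop = FALSE],
        channelNames = recording@channelNames,
        rateHz = sampleRate(recording),
        subjectId = recording@subjectId,
        label = recording@label,
        segmentIndex = as.integer(i))
  })
}

#' Full preprocessing chain
#'
#' Filter at the source rate, resample to the target rate, then segment:
#' band-pass (default 0.5--45 Hz, order 2), resample (default 256 Hz), cut
#' into windows (default 3 s). Passing a `band` name from [eegBands()]
#' replaces the broadband corners with that sub-band's edges.
#'
#' @param recording an [EEGRecording-class].
#' @param lowHz,highHz,order band-pass settings, see [bandpassFilter()].
#' @param targetHz resampling target, see [resampleRecording()].
#' @param lengthS segment length, see [segmentRecording()].
#' @param band optional sub-band name (`"delta"`, `"theta"`, `"alpha"`,
#'   `"beta"`, `"gamma"`) overriding `lowHz`/`highHz`.
#' @return list of [EEGSegment-class].
#' @export
preprocessRecording <- function(recording, lowHz = 0.5, highHz = 45,
                                order = 2L, targetHz = 256, lengthS = 3,
                                band = NULL) {
  if (!is.null(band)) {
    bands <- eegBands()
    if (!band %in% names(bands))
      stop(sprintf("unknown band '%s'; valid: %s", band,
                   paste(names(bands), collapse = ", ")))
    lowHz <- bands[[band]][1]
    highHz <- bands[[band]][2]
  }
  rec <- bandpassFilter(recording, lowHz, highHz, order)
  rec <- resampleRecording(rec, targetHz)
  segmentRecording(rec, lengthS)
}
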