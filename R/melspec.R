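#' @include AllClasses.R
NULL

#' Mel frequency scale
#'
#' The perceptual mel warping `mel(f) = 2595 * log10(1 + f/700)`, which
#' compresses high frequencies relative to low ones, and its inverse.
#'
#' @param fHz frequency (or vector of frequencies) in Hz, >= 0.
#' @param mel mel value(s) to map back to Hz.
#' @return numeric vector of mel values (resp. frequencies in Hz).
#' @examples
#' melScale(0)        # 0
#' melScale(700)      # 2595 * log10(2)
#' melToHz(melScale(12.5))
#' @export
melScale <- function(fHz) {
  if (any(fHz < 0)) stop("'fHz' must be non-negative")
  2595 * log10(1 + fHz / 700)
}

#' @rdname melScale
#' @export
melToHz <- function(mel) {
  if (any(mel < 0)) stop("'mel' must be non-negative")
  700 * (10^(mel / 2595) - 1)
}

#' STFT analysis parameters
#'
#' @param nFft window length in samples. Default 256 (1 s at 256 Hz).
#' @param hop samples between successive frames. Default 32.
#' @param window taper name; `"hamming"` (default) or `"hann"`.
#' @return validated named list with elements `nFft`, `hop`, `window`.
#' @seealso [computeSTFT()]
#' @export
stftParams <- function(nFft = 256L, hop = 32L, window = "hamming") {
  nFft <- as.integer(nFft); hop <- as.integer(hop)
  if (!(hop > 0L && hop <= nFft))
    stop("need 0 < hop <= nFft")
  window <- match.arg(window, c("hamming", "hann"))
  list(nFft = nFft, hop = hop, window = window)
}

#' Mel filter-bank parameters
#'
#' @param nMels number of triangular filters. Default 64.
#' @param fMinHz,fMaxHz frequency range covered by the bank. Defaults 0.5
#'   and 45 Hz, matching the band-pass of the preprocessing step.
#' @param logEps floor added to the mel power before the log compression.
#' @return validated named list.
#' @seealso [melFilterbank()], [segmentToImage()]
#' @export
melParams <- function(nMels = 64L, fMinHz = 0.5, fMaxHz = 45,
                      logEps = 1e-10) {
  nMels <- as.integer(nMels)
  if (nMels < 2L) stop("'nMels' must be >= 2")
  if (!(0 <= fMinHz && fMinHz < fMaxHz))
    stop("need 0 <= fMinHz < fMaxHz")
  if (logEps <= 0) stop("'logEps' must be positive")
  list(nMels = nMels, fMinHz = fMinHz, fMaxHz = fMaxHz, logEps = logEps)
}

.taper <- function(n, window) {
  k <- seq_len(n) - 1L
  switch(window,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)))
}

#' Short-time Fourier transform
#'
#' One-sided STFT of a single signal: frame `t` (0-based) covers samples
#' `[t * hop, t * hop + nFft)`, each frame is tapered (Hamming by default)
#' and transformed, and bins 0..nFft/2 are kept.
#'
#' @param x numeric signal vector, length >= `nFft`.
#' @param params an [stftParams()] list.
#' @param rateHz sampling rate, stored as attributes for axis bookkeeping.
#' @return complex matrix, frames x (nFft/2 + 1), with attributes
#'   `freqHz` (bin centre frequencies) and `timeS` (frame start times).
#' @examples
#' x <- sin(2 * pi * 10 * (0:767) / 256)
#' S <- computeSTFT(x, stftParams(), 256)
#' dim(S)  # 17 x 129
#' @export
computeSTFT <- function(x, params = stftParams(), rateHz = 256) {
  nFft <- params$nFft; hop <- params$hop
  if (length(x) < nFft)
    stop(sprintf("signal has %d samples but the STFT window needs %d",
                 length(x), nFft))
  nFrames <- (length(x) - nFft) %/% hop + 1L
  w <- .taper(nFft, params$window)
  frames <- vapply(seq_len(nFrames) - 1L,
                   function(t) x[(t * hop + 1L):(t * hop + nFft)] * w,
                   numeric(nFft))
  spec <- stats::mvfft(frames)[seq_len(nFft %/% 2L + 1L), , drop = FALSE]
  out <- t(spec)
  attr(out, "freqHz") <- (0:(nFft %/% 2L)) * rateHz / nFft
  attr(out, "timeS") <- (seq_len(nFrames) - 1L) * hop / rateHz
  out
}

#' Triangular mel filter bank
#'
#' Builds `nMels` overlapping triangular filters whose centres are equally
#' spaced on the mel axis between `fMinHz` and `fMaxHz`; triangles are
#' narrow at low frequencies and widen with frequency, mirroring the mel
#' scale. Rows are evaluated on the one-sided FFT bin frequencies.
#'
#' @param params a [melParams()] list.
#' @param nFft FFT length the bank will be applied to.
#' @param rateHz sampling rate in Hz.
#' @return numeric matrix, nMels x (nFft/2 + 1), with attribute
#'   `centerHz` (the filter centre frequencies).
#' @examples
#' fb <- melFilterbank(melParams(), 256, 256)
#' dim(fb)  # 64 x 129
#' @export
melFilterbank <- function(params = melParams(), nFft = 256L, rateHz = 256) {
  nMels <- params$nMels
  if (params$fMaxHz > rateHz / 2)
    stop("'fMaxHz' must not exceed the Nyquist frequency")
  melPts <- seq(melScale(params$fMinHz), melScale(params$fMaxHz),
                length.out = nMels + 2L)
  hzPts <- melToHz(melPts)
  binHz <- (0:(nFft %/% 2L)) * rateHz / nFft
  fb <- matrix(0, nrow = nMels, ncol = length(binHz))
  for (m in seq_len(nMels)) {
    lo <- hzPts[m]; ctr <- hzPts[m + 1L]; hi <- hzPts[m + 2L]
    up <- (binHz - lo) / (ctr - lo)
    down <- (hi - binHz) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  if (any(rowSums(fb) == 0))
    stop(sprintf(paste0("empty mel filters: %d mel bands cannot be resolved ",
                        "by %d-point FFT bins at %g Hz; reduce 'nMels' or ",
                        "increase 'nFft'"), nMels, nFft, rateHz))
  attr(fb, "centerHz") <- hzPts[2:(nMels + 1L)]
  attr(fb, "edgesHz") <- hzPts          # triangle corner frequencies
  fb
}

# 0..255 -> RGB lookup table (rows = levels).
.colormapLut <- function(colormap) {
  if (colormap == "gray")
    return(matrix(rep(0:255, 3), ncol = 3))
  cols <- grDevices::hcl.colors(256, palette = colormap)
  t(grDevices::col2rgb(cols))
}

#' Render an EEG segment as a mel-spectrogram image
#'
#' Per channel, the squared-magnitude STFT is projected through the mel
#' filter bank; per-channel mel power spectrograms are averaged (in the
#' power domain, in channel-name order so the result is independent of the
#' input channel ordering); the average is log-compressed with a small
#' floor, min-max scaled to 0--255, bilinearly resized to `size` x `size`
#' and passed through a colormap to a 3-channel integer image. Time runs
#' along the x-axis and mel frequency along the y-axis with low
#' frequencies at the bottom. A constant (zero-range) spectrogram maps to
#' mid-gray (level 128).
#'
#' @param segment an [EEGSegment-class] (any channel count >= 1).
#' @param stft an [stftParams()] list.
#' @param mel a [melParams()] list.
#' @param size output image side in pixels. Default 224.
#' @param colormap `"viridis"` (default, perceptually uniform) or `"gray"`.
#' @param region region tag stored in the image metadata.
#' @return a [MelImage-class].
#' @examples
#' seg <- new("EEGSegment", data = matrix(rnorm(2 * 768), 2),
#'            channelNames = c("O1", "O2"), rateHz = 256,
#'            subjectId = "s01", label = "HC", segmentIndex = 0L)
#' img <- segmentToImage(seg)
#' dim(imagePixels(img))  # 224 224 3
#' @export
segmentToImage <- function(segment, stft = stftParams(), mel = melParams(),
                           size = 224L, colormap = "viridis",
                           region = "full") {
  stopifnot(is(segment, "EEGSegment"))
  if (nChannels(segment) < 1L) stop("segment has no channels")
  rate <- sampleRate(segment)
  fb <- melFilterbank(mel, stft$nFft, rate)
  ord <- order(toupper(channelNames(segment)))  # canonical aggregation order
  acc <- NULL
  for (ch in ord) {
    S <- computeSTFT(signalData(segment)[ch, ], stft, rate)
    p <- fb %*% t(Mod(S)^2)                     # nMels x nFrames
    acc <- if (is.null(acc)) p else acc + p
  }
  melPower <- acc / nChannels(segment)
  logMel <- log(melPower + mel$logEps)
  rng <- range(logMel)
  scaled <- if (rng[2] > rng[1])
    (logMel - rng[1]) / (rng[2] - rng[1]) * 255
  else
    matrix(128, nrow(logMel), ncol(logMel))
  # rows = mel (low first), cols = time; EBImage treats dim1 as x, so feed
  # the matrix as-is and reorient after the square resize
  resized <- EBImage::imageData(EBImage::resize(
    EBImage::Image(scaled), w = size, h = size, filter = "bilinear"))
  levels <- pmin(255L, pmax(0L, as.integer(round(resized))))
  dim(levels) <- c(size, size)                  # [mel, time]
  lut <- .colormapLut(colormap)
  pix <- array(0L, dim = c(size, size, 3L))
  flip <- seq.int(size, 1L)                     # low mel at the bottom row
  for (k in 1:3) {
    chan <- matrix(lut[levels + 1L, k], size, size)
    pix[, , k] <- chan[flip, , drop = FALSE]
  }
  new("MelImage", pixels = pix,
      subjectId = subjectId(segment), label = classLabel(segment),
      segmentIndex = segment@segmentIndex, region = as.character(region))
}
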