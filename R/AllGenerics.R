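#' @include AllClasses.R
NULL

#' Accessors for EEG containers
#'
#' Small generic accessors shared by [EEGRecording-class] and
#' [EEGSegment-class]: the signal matrix, channel names, sampling rate,
#' subject id and class label.
#'
#' @param object an `EEGRecording` or `EEGSegment`.
#' @return `signalData()` the channels x samples matrix; `channelNames()`
#'   a character vector; `sampleRate()` the rate in Hz; `subjectId()` and
#'   `classLabel()` single strings; `nChannels()`/`nSamples()` integers.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 2), c("Fp1", "O1"), 100, "s1", "HC")
#' channelNames(rec)
#' nSamples(rec)
#' @name eeg-accessors
#' @aliases signalData channelNames sampleRate subjectId classLabel
#'   nChannels nSamples
NULL

#' @rdname eeg-accessors
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))

#' @rdname eeg-accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname eeg-accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname eeg-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname eeg-accessors
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))

#' @rdname eeg-accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname eeg-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

for (cls in c("EEGRecording", "EEGSegment")) {
  setMethod("signalData", cls, function(object) object@data)
  setMethod("channelNames", cls, function(object) object@channelNames)
  setMethod("sampleRate", cls, function(object) object@rateHz)
  setMethod("subjectId", cls, function(object) object@subjectId)
  setMethod("classLabel", cls, function(object) object@label)
  setMethod("nChannels", cls, function(object) nrow(object@data))
  setMethod("nSamples", cls, function(object) ncol(object@data))
}

#' Lobe-table accessors
#'
#' @param object a [LobeTable-class].
#' @param lobe a lobe name present in the table.
#' @return `lobeNames()` the lobe names; `lobeChannels()` the ordered
#'   channel list of one lobe; `fullChannels()` the ordered union.
#' @examples
#' tab <- lobeTable("repod19")
#' lobeNames(tab)
#' lobeChannels(tab, "occipital")
#' @name lobe-accessors
#' @aliases lobeNames lobeChannels fullChannels
NULL

#' @rdname lobe-accessors
#' @export
setGeneric("lobeNames", function(object) standardGeneric("lobeNames"))

#' @rdname lobe-accessors
#' @export
setGeneric("lobeChannels", function(object, lobe) standardGeneric("lobeChannels"))

#' @rdname lobe-accessors
#' @export
setGeneric("fullChannels", function(object) standardGeneric("fullChannels"))

setMethod("lobeNames", "LobeTable", function(object) names(object@lobes))

setMethod("lobeChannels", "LobeTable", function(object, lobe) {
  if (!lobe %in% names(object@lobes))
    stop(sprintf("unknown lobe '%s'; available: %s", lobe,
                 paste(names(object@lobes), collapse = ", ")))
  object@lobes[[lobe]]
})

setMethod("fullChannels", "LobeTable", function(object) object@full)

#' Pixel data of a mel-spectrogram image
#'
#' @param object a [MelImage-class].
#' @return the height x width x 3 integer pixel array.
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))

setMethod("imagePixels", "MelImage", function(object) object@pixels)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, object@label, nrow(object@data),
              ncol(object@data), object@rateHz, ncol(object@data) / object@rateHz))
  cat("  channels:", paste(head(object@channelNames, 8), collapse = ", "),
      if (length(object@channelNames) > 8) "..." else "", "\n")
})

setMethod("show", "EEGSegment", function(object) {
  cat(sprintf("EEGSegment '%s' (%s) #%d: %d channels x %d samples @ %g Hz\n",
              object@subjectId, object@label, object@segmentIndex,
              nrow(object@data), ncol(object@data), object@rateHz))
})

setMethod("show", "LobeTable", function(object) {
  cat(sprintf("LobeTable '%s' (%d channels)\n", object@datasetId,
              length(object@full)))
  for (lb in names(object@lobes))
    cat(sprintf("  %-9s: %s\n", lb, paste(object@lobes[[lb]], collapse = ", ")))
})

setMethod("show", "MelImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MelImage %dx%dx%d [%s/%s seg %d region '%s'] range [%d, %d]\n",
              d[1], d[2], d[3], object@subjectId, object@label,
              object@segmentIndex, object@region,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "CNNClassifier", function(object) {
  cfg <- object@config
  cat(sprintf("CNNClassifier: input %dx%dx%d, %d conv blocks x %d filters, dense %d, classes [%s]\n",
              cfg$inputSize, cfg$inputSize, cfg$inputChannels,
              cfg$nConvBlocks, cfg$nFilters, cfg$denseUnits,
              paste(object@classes, collapse = ", ")))
  cat(sprintf("  parameters: %s; trained: %s\n",
              format(countParams(object@config), big.mark = ","), object@trained))
  if (nrow(object@history))
    cat(sprintf("  last epoch: loss %.4f, accuracy %.3f\n",
                tail(object@history$loss, 1), tail(object@history$accuracy, 1)))
})

setMethod("show", "FoldReport", function(object) {
  cat(sprintf("FoldReport %d: TP %d FP %d TN %d FN %d | Acc %.2f%% AUC %.3f\n",
              object@foldIndex, object@counts["TP"], object@counts["FP"],
              object@counts["TN"], object@counts["FN"],
              object@metrics["accuracy"], object@auc))
})

setMethod("show", "RegionResult", function(object) {
  cat(sprintf("RegionResult '%s' (%d folds), pooled AUC %.3f\n",
              object@region, length(object@folds), object@pooledAuc))
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s %6.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
})
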