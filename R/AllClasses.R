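#' @include lobemel-package.R
NULL

.CLASS_LABELS <- c("HC", "ScZ")

#' Continuous multichannel EEG recording
#'
#' Container for one subject's continuous EEG: a channels-by-samples numeric
#' matrix (microvolt-scaled arbitrary units) plus channel names, sampling
#' rate, subject identifier and class label (`"HC"` or `"ScZ"`).
#'
#' @slot data numeric matrix, channels in rows, samples in columns.
#' @slot channelNames character vector, one label per row of `data`.
#' @slot rateHz sampling rate in Hz.
#' @slot subjectId subject identifier.
#' @slot label class label, `"HC"` or `"ScZ"`.
#'
#' @seealso [EEGRecording()] for the user-facing constructor.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    data = "matrix",
    channelNames = "character",
    rateHz = "numeric",
    subjectId = "character",
    label = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "'data' must be a numeric matrix")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, sprintf("number of channels (%d) != number of channel names (%d)",
                          nrow(object@data), length(object@channelNames)))
  if (anyDuplicated(toupper(trimws(object@channelNames))))
    msg <- c(msg, "channel names must be unique (case-insensitive)")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "'data' contains non-finite values")
  if (length(object@rateHz) != 1L || !is.finite(object@rateHz) || object@rateHz <= 0)
    msg <- c(msg, "'rateHz' must be a single positive number")
  if (length(object@label) != 1L || !object@label %in% .CLASS_LABELS)
    msg <- c(msg, "'label' must be \"HC\" or \"ScZ\"")
  if (length(msg)) msg else TRUE
})

#' Fixed-length EEG segment
#'
#' A short window cut from a preprocessed [EEGRecording-class], carrying the
#' recording's channel ordering, label and a 0-based segment index.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot channelNames character vector of channel labels.
#' @slot rateHz sampling rate in Hz (256 after the default pipeline).
#' @slot subjectId subject identifier of the parent recording.
#' @slot label inherited class label.
#' @slot segmentIndex 0-based index of the window within the recording.
#'
#' @exportClass EEGSegment
setClass("EEGSegment",
  representation(
    data = "matrix",
    channelNames = "character",
    rateHz = "numeric",
    subjectId = "character",
    label = "character",
    segmentIndex = "integer"
  )
)

setValidity("EEGSegment", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "number of channels != number of channel names")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "'data' contains non-finite values")
  if (length(object@segmentIndex) != 1L || object@segmentIndex < 0L)
    msg <- c(msg, "'segmentIndex' must be a single non-negative integer")
  if (length(object@label) != 1L || !object@label %in% .CLASS_LABELS)
    msg <- c(msg, "'label' must be \"HC\" or \"ScZ\"")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Describes a synthetic EEG cohort: sample size per class, recording
#' duration and source rate, which built-in channel set to emulate, where
#' (lobes) and in which frequency band the class effect is planted, its
#' amplitude relative to background, the spectral slope of the 1/f^alpha
#' background, and the master seed.
#'
#' @slot nSubjectsPerClass subjects per class (HC and ScZ).
#' @slot durationS recording duration per subject, seconds.
#' @slot sourceRateHz source sampling rate in Hz (e.g. 250 or 1024).
#' @slot channelSet `"repod19"` or `"kaggle19"`.
#' @slot effectLobes lobe names receiving the class effect.
#' @slot effectBandHz length-2 numeric, effect band (low, high) in Hz.
#' @slot effectSnr RMS of the planted oscillation relative to background RMS.
#' @slot noiseExponent spectral slope alpha of the 1/f^alpha background.
#' @slot seed master seed; (spec, seed) fully determines the cohort.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nSubjectsPerClass = "integer",
    durationS = "numeric",
    sourceRateHz = "numeric",
    channelSet = "character",
    effectLobes = "character",
    effectBandHz = "numeric",
    effectSnr = "numeric",
    noiseExponent = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjectsPerClass < 1L)
    msg <- c(msg, "'nSubjectsPerClass' must be >= 1")
  if (object@durationS <= 0)
    msg <- c(msg, "'durationS' must be positive")
  if (length(object@effectBandHz) != 2L ||
      !(0 < object@effectBandHz[1] && object@effectBandHz[1] < object@effectBandHz[2] &&
        object@effectBandHz[2] < object@sourceRateHz / 2))
    msg <- c(msg, "'effectBandHz' must satisfy 0 < low < high < sourceRateHz/2")
  if (object@effectSnr < 0)
    msg <- c(msg, "'effectSnr' must be non-negative")
  if (object@noiseExponent < 0 || object@noiseExponent > 2)
    msg <- c(msg, "'noiseExponent' must lie in [0, 2]")
  tab <- tryCatch(lobeTable(object@channelSet), error = function(e) NULL)
  if (is.null(tab)) {
    msg <- c(msg, sprintf("unknown channel set '%s'", object@channelSet))
  } else if (!all(object@effectLobes %in% lobeNames(tab))) {
    bad <- setdiff(object@effectLobes, lobeNames(tab))
    msg <- c(msg, sprintf("unknown effect lobe(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Lobe-to-channel mapping for a montage
#'
#' Maps the five lobe names (frontal, central, temporal, parietal,
#' occipital) to ordered channel-name lists for one dataset's montage,
#' together with the full ordered channel union.
#'
#' @slot datasetId montage identifier, e.g. `"repod19"`.
#' @slot lobes named list of character vectors, one per lobe.
#' @slot full ordered union of all lobe channels.
#'
#' @seealso [lobeTable()], [applyMontage()]
#' @exportClass LobeTable
setClass("LobeTable",
  representation(
    datasetId = "character",
    lobes = "list",
    full = "character"
  )
)

setValidity("LobeTable", function(object) {
  msg <- character()
  chans <- unlist(object@lobes, use.names = FALSE)
  if (anyDuplicated(toupper(chans)))
    msg <- c(msg, "lobe channel lists must be pairwise disjoint")
  if (!setequal(toupper(object@full), toupper(chans)))
    msg <- c(msg, "'full' must be the union of the lobe channel lists")
  if (length(object@full) != length(chans))
    msg <- c(msg, "'full' must contain each channel exactly once")
  if (is.null(names(object@lobes)) || any(!nzchar(names(object@lobes))))
    msg <- c(msg, "'lobes' must be a named list")
  if (length(msg)) msg else TRUE
})

#' Rendered mel-spectrogram image
#'
#' A fixed-size integer RGB image (values 0--255) produced from one EEG
#' segment, with provenance: subject, label, segment index and the montage
#' region the channels came from.
#'
#' @slot pixels integer array, height x width x 3, values in \[0, 255\].
#'   Row 1 is the top of the image; low mel frequencies sit at the bottom.
#' @slot subjectId subject identifier.
#' @slot label class label.
#' @slot segmentIndex 0-based segment index.
#' @slot region montage region name (a lobe or `"full"`).
#'
#' @seealso [segmentToImage()]
#' @exportClass MelImage
setClass("MelImage",
  representation(
    pixels = "array",
    subjectId = "character",
    label = "character",
    segmentIndex = "integer",
    region = "character"
  )
)

setValidity("MelImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "'pixels' must be a height x width x 3 array")
  if (!is.integer(object@pixels))
    msg <- c(msg, "'pixels' must be integer-valued")
  else if (min(object@pixels) < 0L || max(object@pixels) > 255L)
    msg <- c(msg, "'pixels' values must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' Convolutional network classifier
#'
#' A four-block convolutional network (32 3x3 filters per block, 2x2 max
#' pooling, dropout 0.25 after blocks 2 and 4, a 256-unit dense layer with
#' dropout 0.5, and a 2-unit softmax output) together with its weights,
#' class order and training history.
#'
#' @slot config named list describing the architecture (see [cnnConfig()]).
#' @slot weights named list of weight arrays.
#' @slot classes class order of the softmax output, `c("HC", "ScZ")`.
#' @slot history data frame of per-epoch training loss and accuracy.
#' @slot trained logical; `TRUE` after [trainModel()].
#'
#' @seealso [buildModel()], [trainModel()], [predictProba()]
#' @exportClass CNNClassifier
setClass("CNNClassifier",
  representation(
    config = "list",
    weights = "list",
    classes = "character",
    history = "data.frame",
    trained = "logical"
  )
)

#' Single cross-validation fold report
#'
#' Confusion counts (ScZ positive), the six headline metrics on the percent
#' scale, and the ROC curve of one held-out fold.
#'
#' @slot foldIndex 1-based fold number.
#' @slot counts named numeric: TP, FP, TN, FN.
#' @slot metrics named numeric: sensitivity, specificity, precision,
#'   accuracy, f1, fpr (percent).
#' @slot roc data frame with columns threshold, fpr, tpr.
#' @slot auc area under the ROC curve (trapezoid rule).
#'
#' @exportClass FoldReport
setClass("FoldReport",
  representation(
    foldIndex = "integer",
    counts = "numeric",
    metrics = "numeric",
    roc = "data.frame",
    auc = "numeric"
  )
)

setValidity("FoldReport", function(object) {
  msg <- character()
  if (!all(c("TP", "FP", "TN", "FN") %in% names(object@counts)))
    msg <- c(msg, "'counts' must contain TP, FP, TN, FN")
  m <- object@metrics[is.finite(object@metrics)]
  if (length(m) && (min(m) < 0 || max(m) > 100))
    msg <- c(msg, "metrics must lie in [0, 100] percent")
  if (length(msg)) msg else TRUE
})

#' Aggregated per-region cross-validation result
#'
#' Per-fold reports plus mean and sample standard deviation (over folds) of
#' every metric, and a pooled ROC built from concatenated out-of-fold
#' scores.
#'
#' @slot region montage region name.
#' @slot folds list of [FoldReport-class] objects.
#' @slot summary data frame: metric, mean, sd.
#' @slot pooledRoc data frame with columns threshold, fpr, tpr.
#' @slot pooledAuc AUC of the pooled ROC.
#'
#' @exportClass RegionResult
setClass("RegionResult",
  representation(
    region = "character",
    folds = "list",
    summary = "data.frame",
    pooledRoc = "data.frame",
    pooledAuc = "numeric"
  )
)
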