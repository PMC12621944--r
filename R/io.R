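#' @include AllClasses.R
NULL

# Fixed-width ASCII header field, right-padded with spaces.
.edfField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

# Numeric formatted to fit an 8-character EDF header field.
.edfNum8 <- function(x) {
  for (digits in 7:1) {
    s <- formatC(x, format = "g", digits = digits)
    if (nchar(s) <= 8) return(s)
  }
  stop(sprintf("cannot format %g into 8 characters", x))
}

#' Write a recording to an EDF file
#'
#' Standard European Data Format: 16-bit samples, one-second data records,
#' physical units microvolts with a symmetric per-channel physical range.
#' The subject id is stored in the patient field and the class label in
#' the recording field. The sampling rate must be an integer (samples per
#' one-second record); a trailing partial second is dropped.
#'
#' @param recording an [EEGRecording-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [readEDF()], [writeCohort()]
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  rate <- sampleRate(recording)
  if (rate != round(rate))
    stop("EDF export needs an integer sampling rate (samples per 1-s record)")
  rate <- as.integer(rate)
  ns <- nChannels(recording)
  nRec <- nSamples(recording) %/% rate
  if (nRec < 1L) stop("recording is shorter than one 1-second data record")
  data <- recording@data[, seq_len(nRec * rate), drop = FALSE]

  # symmetric physical range per channel, rendered exactly as stored
  physMax <- vapply(seq_len(ns), function(ch) {
    a <- max(abs(data[ch, ]), 1e-6) * 1.0001
    repeat {
      s <- .edfNum8(a)
      if (as.numeric(s) >= max(abs(data[ch, ]))) return(as.numeric(s))
      a <- a * 1.01
    }
  }, 0)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edfField(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(subjectId(recording), 80)
  wr(classLabel(recording), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr("", 44)
  wr(nRec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (ch in channelNames(recording)) wr(ch, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(.edfNum8(-physMax[i]), 8)
  for (i in seq_len(ns)) wr(.edfNum8(physMax[i]), 8)
  for (i in seq_len(ns)) wr("-32767", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(rate, 8)
  for (i in seq_len(ns)) wr("", 32)

  gain <- physMax / 32767
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * rate + 1L):(r * rate)
    for (ch in seq_len(ns)) {
      d <- as.integer(pmin(32767, pmax(-32767,
             round(data[ch, cols] / gain[ch]))))
      writeBin(d, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads a standard EDF file (16-bit continuous signals), honouring the
#' per-channel physical scaling. All signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @param label optional class label override; by default the recording
#'   field is used when it matches `"HC"`/`"ScZ"`, else `"HC"`.
#' @return an [EEGRecording-class].
#' @export
readEDF <- function(path, label = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                        # version
  patient <- rd(80)
  recordingField <- rd(80)
  rd(8); rd(8)                 # date, time
  rd(8)                        # header bytes
  rd(44)                       # reserved
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)        # transducer
  for (i in seq_len(ns)) rd(8)         # physical dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)        # prefiltering
  sampPerRec <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)        # reserved
  if (length(unique(sampPerRec)) != 1L)
    stop("EDF signals with differing sampling rates are not supported")
  spr <- sampPerRec[1]
  rate <- spr / recDur
  data <- matrix(0, nrow = ns, ncol = nRec * spr)
  for (r in seq_len(nRec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr, size = 2L, signed = TRUE,
                   endian = "little")
      phys <- (d - digMin[ch]) * (physMax[ch] - physMin[ch]) /
        (digMax[ch] - digMin[ch]) + physMin[ch]
      data[ch, ((r - 1L) * spr + 1L):(r * spr)] <- phys
    }
  }
  if (is.null(label))
    label <- if (recordingField %in% .CLASS_LABELS) recordingField else "HC"
  EEGRecording(data, labels, rate, if (nzchar(patient)) patient else "subject",
               label)
}

#' Write a cohort to EDF files plus a manifest
#'
#' One EDF file per subject and a `manifest.csv` with columns
#' `subject_id`, `label`, `file`, so synthetic and real recordings can
#' share all downstream code.
#'
#' @param cohort list of [EEGRecording-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    fn <- sprintf("%s.edf", subjectId(rec))
    writeEDF(rec, file.path(dir, fn))
    data.frame(subject_id = subjectId(rec), label = classLabel(rec),
               file = fn)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' @param manifestPath path to a `manifest.csv` written by [writeCohort()]
#'   (columns `subject_id`, `label`, `file`; files relative to the
#'   manifest's directory).
#' @return list of [EEGRecording-class].
#' @export
readCohort <- function(manifestPath) {
  man <- read.csv(manifestPath, stringsAsFactors = FALSE)
  base <- dirname(manifestPath)
  lapply(seq_len(nrow(man)), function(i) {
    rec <- readEDF(file.path(base, man$file[i]), label = man$label[i])
    rec@subjectId <- as.character(man$subject_id[i])
    rec
  })
}

#' Read/write a recording as a CSV matrix
#'
#' Fallback plain-text format: one column per channel with a header row
#' of channel names, one row per sample.
#'
#' @param path CSV path.
#' @param rateHz sampling rate of the stored signal.
#' @param subjectId,label metadata to attach on read.
#' @param recording an [EEGRecording-class] to write.
#' @return `readRecordingCSV()` an [EEGRecording-class];
#'   `writeRecordingCSV()` invisibly the path.
#' @export
readRecordingCSV <- function(path, rateHz, subjectId = "subject",
                             label = "HC") {
  df <- read.csv(path, check.names = FALSE)
  data <- unname(t(as.matrix(df)))
  EEGRecording(data, colnames(df), rateHz, subjectId, label)
}

#' @rdname readRecordingCSV
#' @export
writeRecordingCSV <- function(recording, path) {
  df <- as.data.frame(t(signalData(recording)))
  colnames(df) <- channelNames(recording)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
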