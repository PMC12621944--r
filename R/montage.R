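#' @include AllClasses.R
NULL

# Built-in lobe tables. Channel labels reproduce each dataset's printed
# montage verbatim; no aliasing between older (T3/T4/T5/T6) and modern
# (T7/T8) temporal nomenclature is attempted.
.LOBE_TABLES <- list(
  repod19 = list(
    frontal   = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz"),
    central   = c("C3", "C4", "Cz"),
    temporal  = c("T3", "T4", "T5", "T6"),
    parietal  = c("P3", "P4", "Pz"),
    occipital = c("O1", "O2")
  ),
  kaggle19 = list(
    frontal   = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"),
    central   = c("C3", "Cz", "C4"),
    temporal  = c("T7", "T8", "TP7", "TP8"),
    parietal  = c("P3", "Pz", "P4"),
    occipital = c("O1", "O2")
  )
)

# Acquisition channel order of the emulated 19-channel resting-state montage;
# used as the "full" ordering so that simulated recordings look like the
# real files rather than lobe-sorted ones.
.REPOD_ORDER <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                  "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

.makeLobeTable <- function(datasetId, lobes, full = NULL) {
  if (is.null(full)) full <- unlist(lobes, use.names = FALSE)
  new("LobeTable", datasetId = datasetId, lobes = lobes, full = full)
}

#' Built-in lobe channel tables
#'
#' Returns the lobe-to-channel mapping for one of the two built-in
#' montages: `"repod19"`, the 19-channel 10--20 resting-state montage
#' (frontal Fp1, Fp2, F3, F4, F7, F8, Fz; central C3, C4, Cz; temporal T3,
#' T4, T5, T6; parietal P3, P4, Pz; occipital O1, O2), and `"kaggle19"`,
#' the 19-channel selection from a 64-channel task montage (temporal T7,
#' T8, TP7, TP8; otherwise analogous labels).
#'
#' @param datasetId `"repod19"` or `"kaggle19"`.
#' @return a [LobeTable-class].
#' @examples
#' tab <- lobeTable("repod19")
#' lobeChannels(tab, "frontal")
#' length(fullChannels(tab))  # 19
#' @export
lobeTable <- function(datasetId) {
  if (length(datasetId) != 1L || !datasetId %in% names(.LOBE_TABLES))
    stop(sprintf("unknown dataset id '%s'; valid ids: %s",
                 as.character(datasetId)[1],
                 paste(names(.LOBE_TABLES), collapse = ", ")))
  full <- if (datasetId == "repod19") .REPOD_ORDER else NULL
  .makeLobeTable(datasetId, .LOBE_TABLES[[datasetId]], full)
}

#' Load a custom lobe table from JSON
#'
#' Reads a file of the form
#' `{"dataset_id": "...", "lobes": {"frontal": ["Fp1", ...], ...}}`.
#'
#' @param path path to a JSON file.
#' @return a [LobeTable-class].
#' @export
readLobeTable <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$dataset_id) || is.null(x$lobes))
    stop("JSON lobe table must contain 'dataset_id' and 'lobes'")
  lobes <- lapply(x$lobes, as.character)
  .makeLobeTable(as.character(x$dataset_id), lobes)
}

# Case-insensitive, whitespace-trimmed channel lookup; returns row indices.
.matchChannels <- function(wanted, available) {
  normW <- toupper(trimws(wanted))
  normA <- toupper(trimws(available))
  idx <- match(normW, normA)
  if (anyNA(idx)) {
    missing <- wanted[is.na(idx)]
    stop(sprintf("channel(s) not present in recording: %s",
                 paste(missing, collapse = ", ")))
  }
  idx
}

#' Restrict a recording to a montage region
#'
#' Selects the channels of one lobe (or the full table) from a recording,
#' in the table's order. Matching is case-insensitive and
#' whitespace-trimmed; sample values are untouched. Applying the full table
#' to a denser montage (e.g. 64 channels) realises the 64-to-19 channel
#' selection.
#'
#' @param recording an [EEGRecording-class].
#' @param table a [LobeTable-class].
#' @param region a lobe name in the table, or `"full"`.
#' @return an [EEGRecording-class] restricted to the region's channels.
#' @examples
#' spec <- cohortSpec(nSubjectsPerClass = 1, durationS = 4, seed = 1)
#' rec <- generateCohort(spec)[[1]]
#' occ <- applyMontage(rec, lobeTable("repod19"), "occipital")
#' channelNames(occ)  # O1, O2
#' @export
applyMontage <- function(recording, table, region) {
  stopifnot(is(recording, "EEGRecording"), is(table, "LobeTable"))
  wanted <- if (identical(region, "full")) fullChannels(table)
            else lobeChannels(table, region)
  idx <- .matchChannels(wanted, channelNames(recording))
  new("EEGRecording",
      data = recording@data[idx, , drop = FALSE],
      channelNames = recording@channelNames[idx],
      rateHz = recording@rateHz,
      subjectId = recording@subjectId,
      label = recording@label)
}
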