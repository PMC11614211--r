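# File interchange: EDF recordings, BIDS-style events/electrodes TSV, and
# the ground-truth effect manifest (JSON).
#
# The EDF writer/reader below covers the classic 16-bit EDF layout (one
# record per second, physical units microvolts). Header date/time fields are
# fixed constants so that identical data yield byte-identical files.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stopf("EDF header field '%s' exceeds %d chars", x, width)
  formatC(x, width = -width)
}

edfNum <- function(x, width = 8) {
  for (digits in 7:1) {
    s <- formatC(x, format = "g", digits = digits)
    if (nchar(s) <= width) return(edfPad(s, width))
  }
  stopf("cannot format %g into %d chars", x, width)
}

#' Write a recording to an EDF file
#'
#' Classic 16-bit EDF, physical units microvolts, one data record per second.
#' The recording is zero-padded to a whole number of records. Header
#' date/time fields are fixed so that equal inputs produce byte-identical
#' files.
#'
#' @param rec a [SEEGRecording-class]; the sampling rate must be a whole
#'   number of samples per second.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRecordingEDF <- function(rec, path) {
  stopifnot(is(rec, "SEEGRecording"))
  fs <- rec@sfreqHz
  if (fs != round(fs)) stopf("EDF export requires an integer sampling rate")
  spr <- as.integer(fs)                      # samples per 1 s record
  nch <- nrow(rec@data)
  ns <- ncol(rec@data)
  nrec <- as.integer(ceiling(ns / spr))
  physMin <- apply(rec@data, 1, min)
  physMax <- apply(rec@data, 1, max)
  flat <- physMax - physMin < 1e-9
  physMin[flat] <- physMin[flat] - 1
  physMax[flat] <- physMax[flat] + 1
  digMin <- -32768; digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8), edfPad("X X X X", 80), edfPad("Startdate X X X X", 80),
    edfPad("01.01.85", 8), edfPad("00.00.00", 8),
    edfPad(256 * (nch + 1), 8), edfPad("", 44),
    edfPad(nrec, 8), edfPad("1", 8), edfPad(nch, 4),
    paste(vapply(rec@channelNames, edfPad, "", width = 16), collapse = ""),
    paste(rep(edfPad("", 80), nch), collapse = ""),
    paste(rep(edfPad("uV", 8), nch), collapse = ""),
    paste(vapply(physMin, edfNum, ""), collapse = ""),
    paste(vapply(physMax, edfNum, ""), collapse = ""),
    paste(rep(edfPad(digMin, 8), nch), collapse = ""),
    paste(rep(edfPad(digMax, 8), nch), collapse = ""),
    paste(rep(edfPad("", 80), nch), collapse = ""),
    paste(rep(edfPad(spr, 8), nch), collapse = ""),
    paste(rep(edfPad("", 32), nch), collapse = ""))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  scale <- (digMax - digMin) / (physMax - physMin)
  padded <- nrec * spr
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- matrix(0, nrow = spr, ncol = nch)
    inRange <- idx <= ns
    for (ci in seq_len(nch)) {
      x <- numeric(spr)
      x[inRange] <- rec@data[ci, idx[inRange]]
      d <- round((x - physMin[ci]) * scale[ci] + digMin)
      block[, ci] <- pmin(pmax(d, digMin), digMax)
    }
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads 16-bit EDF files with a common samples-per-record across channels
#' (as written by [writeRecordingEDF()]).
#'
#' @param path EDF file path.
#' @return a [SEEGRecording-class].
#' @export
readRecordingEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                      # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)             # transducer
  for (i in seq_len(nch)) rd(8)              # dimension
  physMin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)             # prefiltering
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1)
    stopf("mixed samples-per-record EDF files are not supported")
  spr1 <- spr[1]
  data <- matrix(0, nrow = nch, ncol = nrec * spr1, dimnames = list(labels, NULL))
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = nch * spr1, size = 2L,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = spr1, ncol = nch)
    cols <- ((r - 1L) * spr1 + 1L):(r * spr1)
    for (ci in seq_len(nch)) {
      data[ci, cols] <- (block[, ci] - digMin[ci]) *
        (physMax[ci] - physMin[ci]) / (digMax[ci] - digMin[ci]) + physMin[ci]
    }
  }
  new("SEEGRecording", data = data, sfreqHz = spr1 / recDur, channelNames = labels)
}

#' Write / read the BIDS-style events table
#'
#' The dialect has columns `onset` (s, from recording start), `duration`
#' (s), `trial_type`, `quantity`, `is_catch`, plus `fixation_dur` and
#' `iti_dur` so the full schedule round-trips.
#'
#' @param schedule schedule `data.frame` from [buildSchedule()].
#' @param path `.tsv` path.
#' @return `path` invisibly (writer); a schedule `data.frame` (reader).
#' @export
writeEventsTSV <- function(schedule, path) {
  checkSchedule(schedule)
  out <- data.frame(onset = schedule$onset_s, duration = STIMULUS_DUR_S,
                    trial_type = schedule$modality, quantity = schedule$quantity,
                    is_catch = as.integer(schedule$is_catch),
                    fixation_dur = schedule$fixation_dur_s,
                    iti_dur = schedule$iti_dur_s)
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsTSV
#' @export
readEventsTSV <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "quantity", "is_catch",
            "fixation_dur", "iti_dur")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stopf("events table '%s' is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  data.frame(onset_s = as.numeric(ev$onset), modality = ev$trial_type,
             quantity = as.integer(ev$quantity),
             is_catch = as.logical(ev$is_catch),
             fixation_dur_s = as.numeric(ev$fixation_dur),
             iti_dur_s = as.numeric(ev$iti_dur), stringsAsFactors = FALSE)
}

#' Write / read the electrode table
#'
#' @param electrodes `data.frame` with columns `name` and `region`.
#' @param path `.tsv` path.
#' @return `path` invisibly (writer); the electrode `data.frame` (reader).
#' @export
writeElectrodesTSV <- function(electrodes, path) {
  miss <- setdiff(c("name", "region"), names(electrodes))
  if (length(miss))
    stopf("electrode table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(electrodes$name)) stopf("duplicate contact names in electrode table")
  utils::write.table(electrodes[, c("name", "region")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeElectrodesTSV
#' @export
readElectrodesTSV <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("name", "region"), names(tab))
  if (length(miss))
    stopf("electrode table '%s' is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  if (anyDuplicated(tab$name)) stopf("duplicate contact names in electrode table")
  tab
}

#' Write / read the ground-truth effect manifest (JSON)
#'
#' @param manifest manifest list from [simulateRecording()].
#' @param path `.json` path.
#' @return `path` invisibly (writer); the manifest list (reader).
#' @export
writeEffectManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeEffectManifest
#' @export
readEffectManifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
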