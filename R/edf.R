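# EDF (European Data Format) reading and writing.
#
# EDF is a fixed-layout binary format: a 256-byte ASCII global header,
# 256 ASCII bytes of per-signal header fields, then data records of
# little-endian 16-bit integers. Amplitudes are affine-mapped between the
# declared physical range (microvolts here) and the 16-bit digital range,
# so a write/read round trip is exact up to one quantisation step
# (physical range / 2^16).

.edfPad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

.edfNum <- function(x, width) {
  s <- vapply(x, function(v) {
    out <- formatC(v, format = "fg", width = 1)
    if (nchar(out) > width)
      out <- substr(formatC(v, format = "g", digits = 6), 1, width)
    out
  }, character(1))
  .edfPad(s, width)
}

.writeEDFRaw <- function(signal, samplesPerRecord, nRecords, recordDuration,
                         channelNames, physMin, physMax, subjectId, path) {
  nSig <- nrow(signal)
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s) writeChar(paste(s, collapse = ""), con,
                                 eos = NULL, useBytes = TRUE)
  wchar(.edfPad("0", 8))
  wchar(.edfPad(subjectId, 80))
  wchar(.edfPad("deepeeg synthetic recording", 80))
  wchar(.edfPad("01.01.00", 8))
  wchar(.edfPad("00.00.00", 8))
  wchar(.edfNum(256 * (1 + nSig), 8))
  wchar(.edfPad("", 44))
  wchar(.edfNum(nRecords, 8))
  wchar(.edfNum(recordDuration, 8))
  wchar(.edfNum(nSig, 4))
  wchar(.edfPad(channelNames, 16))
  wchar(.edfPad(rep("", nSig), 80))
  wchar(.edfPad(rep("uV", nSig), 8))
  wchar(.edfNum(rep(physMin, nSig), 8))
  wchar(.edfNum(rep(physMax, nSig), 8))
  wchar(.edfNum(rep(digMin, nSig), 8))
  wchar(.edfNum(rep(digMax, nSig), 8))
  wchar(.edfPad(rep("", nSig), 80))
  wchar(.edfNum(samplesPerRecord, 8))
  wchar(.edfPad(rep("", nSig), 32))
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRecords)) {
    for (s in seq_len(nSig)) {
      ns <- samplesPerRecord[s]
      idx <- ((r - 1) * ns + 1):(r * ns)
      x <- signal[s, idx]
      dig <- round((x - physMin) / scale + digMin)
      dig <- pmin(pmax(dig, digMin), digMax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Write an EEG recording as an EDF file
#'
#' Writes one-second data records with 16-bit quantisation over the given
#' physical range. The recording must span a whole number of seconds.
#' Seizure annotations are not stored in the EDF itself; use
#' [writeAnnotationSummary()] for the sidecar summary file.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @param physRange symmetric physical range in microvolts (default
#'   `c(-1000, 1000)`, a typical scalp-EEG dynamic range, which keeps the
#'   quantisation step far below signal amplitude).
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path, physRange = c(-1000, 1000)) {
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("writeEDF requires an integer sampling rate")
  n <- nSamples(rec)
  if (n %% fs != 0)
    stop("writeEDF requires a whole number of seconds of signal")
  .writeEDFRaw(signalMatrix(rec), rep(as.integer(fs), nChannels(rec)),
               nRecords = n / fs, recordDuration = 1,
               channelNames = channelNames(rec), physMin = physRange[1],
               physMax = physRange[2], subjectId = subjectId(rec), path)
}

#' Read an EDF file into an EEGRecording
#'
#' Supports continuous EDF with a uniform sampling rate across channels.
#' Annotations are left empty; parse the sidecar summary file with
#' [parseAnnotationSummary()] and attach with [setAnnotations()].
#'
#' @param path EDF file path.
#' @return An [EEGRecording-class] with the signal in physical units and
#'   `fs` taken from the header.
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rchar <- function(n) readChar(con, n, useBytes = TRUE)
  rnum <- function(n) as.numeric(trimws(rchar(n)))
  version <- trimws(rchar(8))
  if (!identical(version, "0")) stop("not an EDF file (bad version field)")
  subjectId <- trimws(rchar(80))
  rchar(80); rchar(8); rchar(8)
  rnum(8)                              # header bytes
  rchar(44)
  nRecords <- rnum(8)
  recDur <- rnum(8)
  nSig <- as.integer(rnum(4))
  if (is.na(nSig) || nSig < 1) stop("corrupt EDF header: no signals")
  rmany <- function(w, numeric = FALSE) {
    vapply(seq_len(nSig), function(i) trimws(rchar(w)), character(1))
  }
  labels <- rmany(16)
  rmany(80); rmany(8)
  physMin <- as.numeric(rmany(8)); physMax <- as.numeric(rmany(8))
  digMin <- as.numeric(rmany(8)); digMax <- as.numeric(rmany(8))
  rmany(80)
  sampPerRec <- as.integer(rmany(8))
  rmany(32)
  if (length(unique(sampPerRec)) != 1)
    stop("unsupported EDF: channels with mixed sampling rates")
  ns <- sampPerRec[1]
  fs <- ns / recDur
  raw <- readBin(con, integer(), n = nRecords * nSig * ns, size = 2,
                 endian = "little")
  if (length(raw) < nRecords * nSig * ns)
    stop("corrupt EDF: truncated data section")
  # records are interleaved: for each record, ns samples of each signal
  dim(raw) <- c(ns, nSig, nRecords)
  signal <- matrix(0, nSig, ns * nRecords)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (s in seq_len(nSig)) {
    dig <- as.vector(raw[, s, ])
    signal[s, ] <- (dig - digMin[s]) * scale[s] + physMin[s]
  }
  eegRecording(signal, fs = fs, channelNames = labels,
               subjectId = if (nzchar(subjectId)) subjectId else "unknown")
}

#' Attach seizure annotations to a recording
#'
#' @param rec an [EEGRecording-class].
#' @param ann data.frame with columns `onset_s`, `offset_s`, `label`, as
#'   returned by [parseAnnotationSummary()].
#' @return The recording with annotations attached (sorted by onset).
#' @export
setAnnotations <- function(rec, ann) {
  eegRecording(signalMatrix(rec), samplingRate(rec), channelNames(rec),
               ann, subjectId(rec))
}
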