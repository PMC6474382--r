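# Minimal EDF (European Data Format) reader/writer for multichannel EEG
# in physical units of microvolt: 16-bit samples, 1-s data records.

padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width)
    stop("EDF header field too long: '", x, "'")
  formatC(x, width = -width)
}

#' Write a recording as EDF
#'
#' 16-bit EDF with 1-second data records and physical units of
#' microvolt. The physical range is a symmetric integer bracket of the
#' signal range per channel, so the round-trip error is at most one
#' 16-bit quantisation step. The artifact mask is not part of EDF and
#' must be carried separately (e.g. the stimulation log).
#'
#' @param eeg an [EEGRecording-class]; its duration is truncated to a
#'   whole number of seconds.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(eeg, path) {
  stopifnot(is(eeg, "EEGRecording"))
  fs <- samplingRate(eeg)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- round(fs)
  nrec <- nSamples(eeg) %/% fs
  if (nrec < 1L) stop("recording shorter than one 1-s data record")
  sig <- signalMatrix(eeg)[seq_len(nrec * fs), , drop = FALSE]
  ns <- ncol(sig)
  labels <- channelNames(eeg)
  if (any(!nzchar(labels))) stop("missing channel labels")

  pmax_ <- pmax(ceiling(apply(abs(sig), 2, max)), 1) + 1
  digMin <- -32768; digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(padField(x, width), con,
                                     nchars = width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                       # local patient id
  wr("Startdate X X X X", 80)             # local recording id
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + ns)), 8)
  wr("", 44)
  wr(as.character(nrec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  for (lb in labels) wr(lb, 16)
  for (j in seq_len(ns)) wr("", 80)       # transducer
  for (j in seq_len(ns)) wr("uV", 8)
  for (j in seq_len(ns)) wr(as.character(-pmax_[j]), 8)
  for (j in seq_len(ns)) wr(as.character(pmax_[j]), 8)
  for (j in seq_len(ns)) wr(as.character(digMin), 8)
  for (j in seq_len(ns)) wr(as.character(digMax), 8)
  for (j in seq_len(ns)) wr("", 80)       # prefiltering
  for (j in seq_len(ns)) wr(as.character(fs), 8)
  for (j in seq_len(ns)) wr("", 32)

  scale <- (2 * pmax_) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(ns)) {
      dig <- round((sig[rows, j] + pmax_[j]) / scale[j]) + digMin
      writeBin(as.integer(pmin(pmax(dig, digMin), digMax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Inverse of [writeEDF()]: parses the header, checks that every signal
#' shares one sampling rate, converts digital values back to physical
#' microvolt, and returns an [EEGRecording-class] with an empty artifact
#' mask.
#'
#' @param path EDF file.
#' @return An [EEGRecording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    x <- readChar(con, width, useBytes = TRUE)
    if (nchar(x, type = "bytes") < width)
      stop("malformed EDF header: truncated at byte ",
           seek(con, NA), " in ", path)
    trimws(x)
  }
  rdNum <- function(width, what) {
    x <- rd(width)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v))
      stop("malformed EDF header: non-numeric ", what,
           " ('", x, "') near byte ", seek(con, NA), " in ", path)
    v
  }
  rd(8)                                    # version
  rd(80); rd(80); rd(8); rd(8)
  rdNum(8, "header length")
  rd(44)
  nrec <- rdNum(8, "record count")
  recDur <- rdNum(8, "record duration")
  ns <- as.integer(rdNum(4, "signal count"))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  if (any(!nzchar(labels))) stop("missing channel labels in ", path)
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i)
    rdNum(8, "physical min"), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i)
    rdNum(8, "physical max"), numeric(1))
  dmin <- vapply(seq_len(ns), function(i)
    rdNum(8, "digital min"), numeric(1))
  dmax <- vapply(seq_len(ns), function(i)
    rdNum(8, "digital max"), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i)
    rdNum(8, "samples per record"), numeric(1))
  for (i in seq_len(ns)) rd(32)

  if (length(unique(spr / recDur)) != 1L)
    stop("sampling rate differs across channels in ", path)
  fs <- spr[1] / recDur
  n <- as.integer(nrec * spr[1])
  sig <- matrix(0, n, ns, dimnames = list(NULL, labels))
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[j], size = 2,
                     signed = TRUE, endian = "little")
      if (length(dig) < spr[j])
        stop("malformed EDF: truncated data record ", r, " in ", path)
      rows <- ((r - 1L) * spr[j] + 1L):(r * spr[j])
      sig[rows, j] <- pmin_[j] + (dig - dmin[j]) * scale[j]
    }
  }
  EEGRecording(sig, fs, labels)
}
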