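## Minimal European Data Format (EDF) reader/writer for continuous
## multichannel recordings with a shared sampling rate. No R EDF package is
## declared as a dependency; the subset implemented here covers the classic
## 16-bit EDF layout: 256-byte fixed header, 256 bytes per signal header,
## then data records of little-endian 16-bit integers.

padField <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as an EDF file
#'
#' Encodes a continuous recording as classic EDF with 1-s data records.
#' Samples are quantized to the 16-bit digital range against per-channel
#' physical extrema, so the round trip is exact to within one quantization
#' step. Trailing samples that do not fill a whole record are dropped.
#'
#' @param recording an \linkS4class{EEGRecording}; the sampling rate must be
#'   a whole number of samples per second.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@samplingRate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer number of samples per second")
  fs <- as.integer(round(fs))
  x <- recording@samples
  ns <- nrow(x)
  nRec <- ncol(x) %/% fs
  if (nRec < 1) stop("recording shorter than one 1-s data record")
  x <- x[, seq_len(nRec * fs), drop = FALSE]

  physMin <- apply(x, 1, min)
  physMax <- apply(x, 1, max)
  flat <- physMax - physMin < 1e-12
  physMax[flat] <- physMin[flat] + 1
  digMin <- -32768L; digMax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField(recording@subjectId, 80),
    padField(paste0("Startdate X sleeptopo t", recording@timePoint), 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * (ns + 1), 8), padField("", 44),
    padField(nRec, 8), padField("1", 8), padField(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(padField(recording@channelLabels, 16), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(padField("uV", 8), ns), collapse = ""),
    paste(padField(formatC(physMin, digits = 7, format = "g"), 8),
          collapse = ""),
    paste(padField(formatC(physMax, digits = 7, format = "g"), 8),
          collapse = ""),
    paste(rep(padField(digMin, 8), ns), collapse = ""),
    paste(rep(padField(digMax, 8), ns), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(padField(fs, 8), ns), collapse = ""),
    paste(rep(padField("", 32), ns), collapse = ""))
  writeChar(sig, con, eos = NULL)

  # re-read the header's printed extrema so the scaling is self-consistent
  physMin <- as.numeric(formatC(physMin, digits = 7, format = "g"))
  physMax <- as.numeric(formatC(physMax, digits = 7, format = "g"))
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    seg <- x[, ((r - 1L) * fs + 1L):(r * fs), drop = FALSE]
    dig <- round((seg - physMin) / gain) + digMin
    dig <- pmin(pmax(dig, digMin), digMax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads a classic EDF file written by \code{\link{writeEDF}} or any EDF with
#' a shared sampling rate across the selected signals; physical units are
#' honored via the per-signal scaling in the header.
#'
#' @param path EDF file path.
#' @param channels optional character vector of signal labels to load (e.g.
#'   the EEG subset of a montage that also carries ocular/myographic leads).
#' @param subjectId,timePoint metadata for the returned object; default
#'   subject id is taken from the EDF patient field.
#' @return an \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path, channels = NULL, subjectId = NULL, timePoint = 1L) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  invisible(rd(8))                      # version
  patient <- rd(80)
  invisible(rd(80)); invisible(rd(8)); invisible(rd(8))
  invisible(rd(8))                      # header bytes
  invisible(rd(44))
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: ", path)
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16)
  invisible(fld(80)); invisible(fld(8))
  physMin <- as.numeric(fld(8)); physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  invisible(fld(80))
  spr <- as.integer(fld(8))
  invisible(fld(32))

  sel <- if (is.null(channels)) seq_len(ns) else match(channels, labels)
  if (any(is.na(sel))) stop("channel(s) absent from EDF: ",
                            paste(channels[is.na(sel)], collapse = ", "))
  if (length(unique(spr[sel])) != 1L)
    stop("selected signals have mixed sampling rates; pass an explicit ",
         "channel subset with a shared rate")
  fs <- spr[sel[1]] / recDur

  recLen <- sum(spr)
  gain <- (physMax - physMin) / (digMax - digMin)
  out <- matrix(0, length(sel), nRec * spr[sel[1]])
  offs <- c(0L, cumsum(spr))
  for (r in seq_len(nRec)) {
    raw <- readBin(con, "integer", n = recLen, size = 2, signed = TRUE,
                   endian = "little")
    if (length(raw) < recLen) stop("truncated EDF data: ", path)
    for (j in seq_along(sel)) {
      i <- sel[j]
      dig <- raw[(offs[i] + 1L):offs[i + 1L]]
      out[j, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (dig - digMin[i]) * gain[i] + physMin[i]
    }
  }
  EEGRecording(out, fs, channelLabels = labels[sel],
               subjectId = if (is.null(subjectId)) patient else subjectId,
               timePoint = timePoint)
}
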