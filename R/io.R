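# Readers and writers for the signal formats the pipeline consumes: EDF and
# BrainVision for EEG, 16-bit PCM WAV for audio/force, and delimited text for
# generic multichannel signals. All readers return a ContinuousRecording.

.padfw <- function(x, width) {
  s <- substr(sprintf("%-*s", width, as.character(x)), 1, width)
  s
}

#' Write a recording as EDF
#'
#' Minimal European Data Format writer: one data record spanning the whole
#' recording, 16-bit samples scaled between the per-channel physical
#' extremes.
#'
#' @param rec a [ContinuousRecording].
#' @param path output `.edf` file.
#' @return the path, invisibly.
#' @export
edfWrite <- function(rec, path) {
  stopifnot(is(rec, "ContinuousRecording"))
  ns <- nChannels(rec)
  n <- ncol(rec@samples)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .padfw("0", 8), .padfw("synthetic", 80), .padfw("synthetic", 80),
    .padfw("01.01.00", 8), .padfw("00.00.00", 8),
    .padfw(256 + ns * 256, 8), .padfw("", 44), .padfw(1, 8),
    .padfw(format(n / rec@fs, nsmall = 0), 8), .padfw(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmin <- apply(rec@samples, 1, min)
  pmax <- apply(rec@samples, 1, max)
  same <- pmax - pmin < .Machine$double.eps
  pmax[same] <- pmin[same] + 1
  fld <- function(vals, width) writeChar(paste0(vapply(vals, .padfw, "", width = width),
                                                collapse = ""), con, eos = NULL)
  fld(rec@channelLabels, 16)
  fld(rep("", ns), 80)                     # transducer
  fld(rep("au", ns), 8)                    # physical dimension
  fld(signif(pmin, 7), 8)
  fld(signif(pmax, 7), 8)
  fld(rep(-32768, ns), 8)
  fld(rep(32767, ns), 8)
  fld(rep("", ns), 80)                     # prefiltering
  fld(rep(n, ns), 8)                       # samples per record
  fld(rep("", ns), 32)
  for (ch in seq_len(ns)) {
    x <- rec@samples[ch, ]
    dig <- round((x - pmin[ch]) / (pmax[ch] - pmin[ch]) * 65535 - 32768)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Supports continuous 16-bit EDF with any record layout; annotations
#' channels are not interpreted.
#'
#' @param path `.edf` file.
#' @return a [ContinuousRecording].
#' @export
edfRead <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  nr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  store <- lapply(seq_len(ns), function(i) numeric(nRec * nr[i]))
  for (rec in seq_len(nRec)) for (ch in seq_len(ns)) {
    dig <- readBin(con, "integer", n = nr[ch], size = 2, endian = "little")
    phys <- pmin[ch] + (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
      (pmax[ch] - pmin[ch])
    store[[ch]][(rec - 1) * nr[ch] + seq_len(nr[ch])] <- phys
  }
  fs <- nr[1] / recDur
  new("ContinuousRecording", samples = do.call(rbind, store), fs = fs,
      channelLabels = labels, t0 = 0,
      processingLog = sprintf("read from EDF %s", basename(path)))
}

#' Write a recording as BrainVision
#'
#' Writes the text header (`.vhdr`) and a binary multiplexed IEEE float-32
#' data file (`.eeg`) next to it.
#'
#' @param rec a [ContinuousRecording].
#' @param path path of the `.vhdr` file.
#' @return the path, invisibly.
#' @export
bvWrite <- function(rec, path) {
  stopifnot(is(rec, "ContinuousRecording"))
  dataFile <- sub("\\.vhdr$", ".eeg", basename(path))
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", dataFile),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nChannels(rec)),
    sprintf("SamplingInterval=%.10g", 1e6 / rec@fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,au", seq_len(nChannels(rec)), rec@channelLabels))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), dataFile), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec@samples), con, size = 4, endian = "little")
  invisible(path)
}

.parseVhdr <- function(lines) {
  kv <- grep("=", lines, value = TRUE, fixed = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(vals, keys)
}

#' Read a BrainVision recording
#'
#' Supports multiplexed binary data in IEEE float-32 or signed 16-bit
#' integer form (per-channel resolutions applied), and vectorized/
#' multiplexed ASCII data.
#'
#' @param path path of the `.vhdr` header.
#' @return a [ContinuousRecording].
#' @export
bvRead <- function(path) {
  lines <- readLines(path, warn = FALSE)
  info <- .parseVhdr(lines)
  nch <- as.integer(info[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(info[["SamplingInterval"]])
  chKeys <- sprintf("Ch%d", seq_len(nch))
  chSpec <- strsplit(unname(info[chKeys]), ",")
  labels <- vapply(chSpec, `[`, "", 1)
  resolution <- vapply(chSpec, function(s)
    if (length(s) >= 3 && nzchar(s[3])) as.numeric(s[3]) else 1, numeric(1))
  dataPath <- file.path(dirname(path), info[["DataFile"]])
  fmt <- toupper(info[["DataFormat"]])
  if (fmt == "BINARY") {
    binFmt <- toupper(info[["BinaryFormat"]])
    sz <- file.info(dataPath)$size
    con <- file(dataPath, "rb")
    on.exit(close(con))
    raw <- if (binFmt == "IEEE_FLOAT_32")
      readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
    else if (binFmt == "INT_16")
      readBin(con, "integer", n = sz / 2, size = 2, endian = "little")
    else stop("unsupported BinaryFormat: ", binFmt)
    m <- matrix(raw, nrow = nch)          # multiplexed: channels vary fastest
    m <- m * resolution
  } else if (fmt == "ASCII") {
    d <- utils::read.table(dataPath, header = FALSE)
    m <- t(as.matrix(d)) * resolution
  } else stop("unsupported DataFormat: ", fmt)
  new("ContinuousRecording", samples = m, fs = fs, channelLabels = labels,
      t0 = 0, processingLog = sprintf("read from BrainVision %s", basename(path)))
}

#' Write a recording as 16-bit PCM WAV
#'
#' Samples are expected within `[-1, 1]` full scale; values outside are
#' clipped with a warning.
#'
#' @param rec a [ContinuousRecording].
#' @param path output `.wav` file.
#' @return the path, invisibly.
#' @export
wavWrite <- function(rec, path) {
  stopifnot(is(rec, "ContinuousRecording"))
  x <- rec@samples
  if (any(abs(x) > 1)) {
    warning("samples outside [-1, 1] clipped for 16-bit WAV export")
    x <- pmin(pmax(x, -1), 1)
  }
  nch <- nrow(x)
  n <- ncol(x)
  pcm <- as.integer(round(as.vector(x) * 32767))  # interleave: channels fastest
  dataBytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + dataBytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(1); w16(nch); w32(round(rec@fs))
  w32(round(rec@fs) * nch * 2); w16(nch * 2); w16(16)
  writeChar("data", con, eos = NULL); w32(dataBytes)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path `.wav` file.
#' @return a [ContinuousRecording] with samples scaled to `[-1, 1]`.
#' @export
wavRead <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  r32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fs <- NULL; nch <- NULL; bits <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) break
    size <- r32()
    if (id == "fmt ") {
      fmt <- r16(); nch <- r16(); fs <- r32(); r32(); r16(); bits <- r16()
      if (fmt != 1 || bits != 16) stop("only 16-bit PCM WAV is supported")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", n = size / 2, size = 2,
                     endian = "little")
      break
    } else readBin(con, "raw", n = size)
  }
  if (is.null(pcm)) stop("no data chunk found in ", path)
  m <- t(matrix(pcm / 32767, ncol = nch, byrow = TRUE))
  new("ContinuousRecording", samples = m, fs = fs,
      channelLabels = paste0("ch", seq_len(nch)), t0 = 0,
      processingLog = sprintf("read from WAV %s", basename(path)))
}

#' Write / read a recording as delimited text
#'
#' Tab-separated table: first column `time` (seconds), remaining columns one
#' per channel with the labels as header.
#'
#' @param rec a [ContinuousRecording].
#' @param path file path.
#' @return `writeDelimitedSignal`: the path invisibly; `readDelimitedSignal`:
#'   a [ContinuousRecording].
#' @export
writeDelimitedSignal <- function(rec, path) {
  stopifnot(is(rec, "ContinuousRecording"))
  n <- ncol(rec@samples)
  d <- data.frame(time = rec@t0 + (seq_len(n) - 1) / rec@fs,
                  t(rec@samples), check.names = FALSE)
  names(d) <- c("time", rec@channelLabels)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDelimitedSignal
#' @export
readDelimitedSignal <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  if (names(d)[1] != "time")
    stop("delimited signal must start with a 'time' column")
  t <- d[[1]]
  if (length(t) < 2) stop("signal too short to infer the sampling rate")
  fs <- 1 / stats::median(diff(t))
  new("ContinuousRecording", samples = t(as.matrix(d[, -1, drop = FALSE])),
      fs = fs, channelLabels = names(d)[-1], t0 = t[1],
      processingLog = sprintf("read from %s", basename(path)))
}
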