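#' Read a recording from a CSV sample matrix with a JSON sidecar
#'
#' The CSV holds one column per channel (header = channel labels), one row
#' per sample. The JSON sidecar (same path with extension `.json`) supplies
#' at least `rate` and optionally `labels`.
#'
#' @param csvPath path to the sample CSV.
#' @param jsonPath path to the sidecar; defaults to `csvPath` with a
#'   `.json` extension.
#' @return a [Recording-class].
#' @export
readRecordingCsv <- function(csvPath,
                             jsonPath = sub("\\.csv$", ".json", csvPath)) {
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  if (is.null(meta$rate)) stop("sidecar must supply the sampling rate")
  m <- as.matrix(read.csv(csvPath, check.names = FALSE))
  labels <- if (!is.null(meta$labels)) meta$labels else colnames(m)
  samples <- t(m)
  dimnames(samples) <- NULL
  recording(samples, rate = meta$rate, labels = labels)
}

#' Write a recording as CSV plus JSON sidecar
#'
#' @param rec a [Recording-class].
#' @param csvPath output CSV path; the sidecar is written next to it.
#' @return invisibly, the CSV path.
#' @export
writeRecordingCsv <- function(rec, csvPath) {
  m <- t(rec@samples)
  colnames(m) <- rec@labels
  write.csv(m, csvPath, row.names = FALSE)
  jsonlite::write_json(list(rate = rec@rate, labels = rec@labels),
                       sub("\\.csv$", ".json", csvPath),
                       auto_unbox = FALSE, digits = NA)
  invisible(csvPath)
}

#' Read annotations
#'
#' Annotation CSVs carry columns `channel`, `start_s`, `end_s`, `kind`
#' (`seizure`, `ied`, `soz`); for instantaneous events (`ied`) `end_s` may
#' equal `start_s`.
#'
#' @param path CSV path.
#' @return a data.frame with those columns.
#' @export
readAnnotations <- function(path) {
  a <- read.csv(path)
  need <- c("channel", "start_s", "end_s", "kind")
  if (!all(need %in% names(a)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  a
}

# ---- Minimal EDF (European Data Format) support -------------------------
# 16-bit EDF with identical rate on all channels, one data record per
# second. Written by hand: the environment provides no R-side EDF codec.
# Binary files are produced at run time only.

#' Write a recording to an EDF file
#'
#' Minimal standard-compliant EDF: 16-bit samples, one-second data records,
#' a common sampling rate for all channels. Physical ranges are set per
#' channel from the data, so a round-trip through [readEdf()] is exact up
#' to 16-bit quantisation of each channel's range.
#'
#' @param rec a [Recording-class] with an integer sampling rate.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEdf <- function(rec, path) {
  fs <- rec@rate
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  ns <- nrow(rec@samples)
  nRec <- ncol(rec@samples) %/% fs
  if (nRec < 1) stop("recording shorter than one EDF data record")
  x <- rec@samples[, seq_len(nRec * fs), drop = FALSE]
  physMin <- apply(x, 1, min); physMax <- apply(x, 1, max)
  physMax[physMax == physMin] <- physMin[physMax == physMin] + 1
  digMin <- -32768; digMax <- 32767
  pad <- function(s, n) formatC(substr(s, 1, n), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("synthetic", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(as.character(256 * (ns + 1)), 8), pad("", 44),
                pad(as.character(nRec), 8), pad("1", 8),
                pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  wf <- function(vals, width) writeChar(paste0(vapply(
    as.character(vals), pad, character(1), n = width), collapse = ""),
    con, eos = NULL)
  wf(rec@labels, 16)                     # label
  wf(rep("", ns), 80)                    # transducer
  wf(rep("uV", ns), 8)                   # physical dimension
  wf(formatC(physMin, format = "g", digits = 6), 8)
  wf(formatC(physMax, format = "g", digits = 6), 8)
  wf(rep(digMin, ns), 8)
  wf(rep(digMax, ns), 8)
  wf(rep("", ns), 80)                    # prefiltering
  wf(rep(fs, ns), 8)                     # samples per record
  wf(rep("", ns), 32)                    # reserved
  # re-read the header's physical ranges so that the round-trip is exact
  physMin <- as.numeric(formatC(physMin, format = "g", digits = 6))
  physMax <- as.numeric(formatC(physMax, format = "g", digits = 6))
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, idx] - physMin[ch]) / gain[ch]) + digMin
      writeBin(as.integer(pmin(pmax(dig, digMin), digMax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Counterpart of [writeEdf()]; supports standard 16-bit EDF with a common
#' sampling rate across channels.
#'
#' @param path EDF path.
#' @return a [Recording-class].
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rdc <- function(n) readChar(con, n, useBytes = TRUE)
  rdc(8 + 80 + 80 + 8 + 8)
  headerBytes <- as.integer(rdc(8))
  rdc(44)
  nRec <- as.integer(rdc(8))
  recDur <- as.numeric(rdc(8))
  ns <- as.integer(rdc(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rdc(16), character(1)))
  rdc(80 * ns); rdc(8 * ns)
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rdc(8), character(1)))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rdc(8), character(1)))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rdc(8), character(1)))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rdc(8), character(1)))
  rdc(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rdc(8), character(1)))
  rdc(32 * ns)
  if (length(unique(spr)) != 1)
    stop("only a common sampling rate across channels is supported")
  fs <- spr[1] / recDur
  seek(con, headerBytes)
  gain <- (physMax - physMin) / (digMax - digMin)
  out <- matrix(0, ns, nRec * spr[1])
  for (r in seq_len(nRec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      out[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - digMin[ch]) * gain[ch] + physMin[ch]
    }
  }
  recording(out, rate = fs, labels = labels)
}
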