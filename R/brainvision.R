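# Minimal BrainVision-dialect I/O: a .vhdr text header, a .vmrk marker file
# and a multiplexed binary .eeg data file, IEEE float-32 or signed 16-bit
# with per-channel resolution scaling. Little-endian throughout.

#' Write a recording as a BrainVision file triplet
#'
#' @param recording a \linkS4class{RawRecording}
#' @param basePath path without extension; .vhdr/.vmrk/.eeg are created
#' @param binaryFormat "IEEE_FLOAT_32" (lossless) or "INT_16" (quantized by
#'   \code{resolution})
#' @param resolution microvolts per bit for INT_16
#' @return the .vhdr path, invisibly
#' @export
writeBrainVision <- function(recording, basePath,
                             binaryFormat = c("IEEE_FLOAT_32", "INT_16"),
                             resolution = 0.1) {
  binaryFormat <- match.arg(binaryFormat)
  if (ncol(recording@samples) == 0 || nrow(recording@samples) == 0)
    stopLabeled("brainvision", "recording is empty")
  base <- basename(basePath)
  vhdr <- paste0(basePath, ".vhdr")
  vmrk <- paste0(basePath, ".vmrk")
  eeg <- paste0(basePath, ".eeg")
  nCh <- nrow(recording@samples)
  res <- if (binaryFormat == "INT_16") resolution else 1
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nCh),
    paste0("SamplingInterval=", format(1e6 / recording@srate, digits = 12)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binaryFormat),
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(nCh), recording@channels,
            format(res, digits = 12)))
  writeLines(hdr, vhdr, useBytes = FALSE)
  writeLines(c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    sprintf("Mk1=New Segment,%s,1,1,0", recording@condition)), vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  x <- as.vector(recording@samples)          # column-major = multiplexed
  if (binaryFormat == "IEEE_FLOAT_32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(x / resolution))
    if (any(q > 32767 | q < -32768))
      stopLabeled("brainvision", "INT_16 overflow at resolution ",
                  resolution, " µV")
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(vhdr)
}

parseIniSection <- function(lines, section) {
  starts <- grep("^\\[", lines)
  hit <- which(trimws(lines[starts]) == paste0("[", section, "]"))
  if (!length(hit)) return(character(0))
  from <- starts[hit[1]] + 1
  to <- if (hit[1] < length(starts)) starts[hit[1] + 1] - 1 else length(lines)
  block <- lines[from:to]
  block[nzchar(trimws(block)) & !grepl("^;", block)]
}

iniValue <- function(block, key) {
  hit <- grep(paste0("^", key, "="), block, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Read a BrainVision file triplet
#'
#' Supports the dialect written by \code{\link{writeBrainVision}}:
#' multiplexed binary data, IEEE float-32 or signed 16-bit with per-channel
#' resolution scaling.
#'
#' @param vhdrPath path to the .vhdr header
#' @param id,condition metadata for the returned recording; condition
#'   defaults to the first marker description when recognizable
#' @return a \linkS4class{RawRecording} (microvolts)
#' @export
readBrainVision <- function(vhdrPath, id = NULL, condition = NULL) {
  if (!file.exists(vhdrPath))
    stopLabeled("brainvision", "header not found: ", vhdrPath)
  lines <- readLines(vhdrPath, warn = FALSE)
  common <- parseIniSection(lines, "Common Infos")
  binary <- parseIniSection(lines, "Binary Infos")
  chans <- parseIniSection(lines, "Channel Infos")
  dataFile <- iniValue(common, "DataFile")
  markerFile <- iniValue(common, "MarkerFile")
  if (is.na(dataFile))
    stopLabeled("brainvision", "header lacks DataFile")
  dir <- dirname(vhdrPath)
  eegPath <- file.path(dir, dataFile)
  if (!file.exists(eegPath))
    stopLabeled("brainvision", "missing companion data file: ", dataFile)
  if (!is.na(markerFile) && !file.exists(file.path(dir, markerFile)))
    stopLabeled("brainvision", "missing companion marker file: ", markerFile)
  orient <- iniValue(common, "DataOrientation")
  if (!is.na(orient) && toupper(orient) != "MULTIPLEXED")
    stopLabeled("brainvision", "unsupported data orientation: ", orient)
  fmt <- toupper(iniValue(binary, "BinaryFormat"))
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stopLabeled("brainvision", "unsupported binary format: ", fmt)
  nCh <- as.integer(iniValue(common, "NumberOfChannels"))
  sampInt <- as.numeric(iniValue(common, "SamplingInterval"))  # microseconds
  if (is.na(nCh) || is.na(sampInt))
    stopLabeled("brainvision", "header lacks NumberOfChannels or ",
                "SamplingInterval")
  chParts <- strsplit(sub("^Ch[0-9]+=", "", chans), ",")
  if (length(chParts) != nCh)
    stopLabeled("brainvision", "header advertises ", nCh, " channels but ",
                "lists ", length(chParts))
  labels <- vapply(chParts, `[`, character(1), 1)
  resolution <- vapply(chParts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))
  sz <- file.size(eegPath)
  bytes <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  if (sz %% (bytes * nCh) != 0)
    stopLabeled("brainvision", "data size ", sz, " bytes is not a multiple ",
                "of ", nCh, " channels x ", bytes, " bytes")
  nSamp <- sz %/% (bytes * nCh)
  con <- file(eegPath, "rb")
  on.exit(close(con))
  raw <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, numeric(), n = nCh * nSamp, size = 4, endian = "little")
  } else {
    readBin(con, integer(), n = nCh * nSamp, size = 2, signed = TRUE,
            endian = "little")
  }
  m <- matrix(raw, nrow = nCh)
  if (fmt == "INT_16") m <- m * resolution
  rownames(m) <- labels
  if (is.null(condition)) {
    mk <- readLines(file.path(dir, markerFile), warn = FALSE)
    desc <- sub("^Mk1=[^,]*,([^,]*),.*$", "\\1", grep("^Mk1=", mk,
                                                      value = TRUE)[1])
    condition <- if (isTRUE(desc %in% c("open", "closed"))) desc else "closed"
  }
  new("RawRecording",
      id = if (is.null(id)) sub("\\.vhdr$", "", basename(vhdrPath)) else id,
      condition = condition, channels = labels, samples = m,
      srate = 1e6 / sampInt)
}
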