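# BrainVision (.vhdr/.vmrk/.eeg) reader and writer.
# Binary data are IEEE float32 (write) or float32/int16 (read), multiplexed.

#' Write a recording as a BrainVision file triplet
#'
#' @param rec an `eeg_recording`
#' @param basepath path without extension; `.vhdr`, `.vmrk`, `.eeg` are added
#' @return invisibly, the `.vhdr` path
#' @export
write_brainvision <- function(rec, basepath) {
  vhdr <- paste0(basepath, ".vhdr")
  vmrk <- paste0(basepath, ".vmrk")
  eegf <- paste0(basepath, ".eeg")
  stem <- basename(basepath)
  nch <- n_channels(rec)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    sprintf("MarkerFile=%s.vmrk", stem),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nch),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$srate),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$channels$name)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    "[Marker Infos]"
  )
  k <- 1L
  lines <- character()
  for (b in rec$boundaries) {
    lines <- c(lines, sprintf("Mk%d=New Segment,,%d,1,0", k, b + 1L)); k <- k + 1L
  }
  if (nrow(rec$events)) {
    for (i in seq_len(nrow(rec$events))) {
      lines <- c(lines, sprintf("Mk%d=Stimulus,%s,%d,1,0", k,
                                rec$events$label[i], rec$events$sample[i] + 1L))
      k <- k + 1L
    }
  }
  writeLines(c(mk, lines), vmrk, useBytes = TRUE)
  con <- file(eegf, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(vhdr)
}

#' Parse a BrainVision INI-style section file into key=value lists
#' @noRd
parse_bv_ini <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sec <- NULL; out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) { sec <- gsub("^\\[|\\]$", "", ln); out[[sec]] <- list(); next }
    if (is.null(sec) || !grepl("=", ln, fixed = TRUE)) next
    kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    out[[sec]][[trimws(kv[1])]] <- trimws(kv[2])
  }
  out
}

#' Read a BrainVision recording
#'
#' Supports BINARY MULTIPLEXED data in IEEE_FLOAT_32 or INT_16 (with
#' per-channel resolution). "New Segment" markers become boundaries; all
#' other markers become events.
#'
#' @param vhdr_path path to the `.vhdr` header file
#' @return an `eeg_recording` (without sidecar metadata)
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("header file not found: ", vhdr_path)
  ini <- parse_bv_ini(vhdr_path)
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  chi <- ini[["Channel Infos"]]
  if (toupper(ci$DataFormat %||% "BINARY") != "BINARY")
    stop("only BINARY BrainVision data supported")
  if (toupper(ci$DataOrientation %||% "MULTIPLEXED") != "MULTIPLEXED")
    stop("only MULTIPLEXED orientation supported")
  nch <- as.integer(ci$NumberOfChannels)
  srate <- 1e6 / as.numeric(ci$SamplingInterval)
  dirn <- dirname(vhdr_path)
  eegf <- file.path(dirn, ci$DataFile)
  vmrk <- if (!is.null(ci$MarkerFile)) file.path(dirn, ci$MarkerFile) else NULL
  chn <- character(nch); res <- rep(1, nch)
  for (i in seq_len(nch)) {
    parts <- strsplit(chi[[sprintf("Ch%d", i)]], ",", fixed = TRUE)[[1]]
    chn[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }
  fmt <- toupper(bi$BinaryFormat %||% "IEEE_FLOAT_32")
  sz <- file.info(eegf)$size
  if (fmt == "IEEE_FLOAT_32") {
    n <- as.integer(sz / 4)
    raw <- readBin(eegf, "numeric", n = n, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    n <- as.integer(sz / 2)
    raw <- readBin(eegf, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  ns <- length(raw) %/% nch
  if (ns < 1) stop("data file contains no complete sample frame: ", eegf)
  data <- matrix(raw[seq_len(ns * nch)], nrow = nch)
  if (fmt == "INT_16" || any(res != 1)) data <- data * res
  events <- data.frame(sample = integer(), label = character())
  boundaries <- integer()
  if (!is.null(vmrk) && file.exists(vmrk)) {
    mi <- parse_bv_ini(vmrk)[["Marker Infos"]]
    for (v in mi) {
      parts <- strsplit(v, ",", fixed = TRUE)[[1]]
      type <- parts[1]; desc <- if (length(parts) >= 2) parts[2] else ""
      pos <- as.integer(parts[3]) - 1L
      if (type == "New Segment") boundaries <- c(boundaries, pos)
      else events <- rbind(events, data.frame(sample = pos, label = desc))
    }
  }
  boundaries <- boundaries[boundaries > 0L]  # a break at 0 is not a break
  eeg_recording(data, srate,
                data.frame(name = chn, type = "EEG", stringsAsFactors = FALSE),
                events = events, boundaries = boundaries)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
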