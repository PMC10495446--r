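# Minimal EDF (European Data Format) continuous reader/writer.
# Fixed-layout ASCII header, 16-bit integer data records, physical scaling
# from the per-signal calibration fields. All signals must share one
# sampling rate (EEG amplifier layout).

read_ascii_field <- function(con, nbytes) trimws(readChar(con, nbytes, useBytes = TRUE))

#' Read a continuous EDF recording
#'
#' @param path path to the `.edf` file
#' @return an `eeg_recording` (without sidecar metadata)
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                  # version
  readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE)    # patient, recording, date, time
  read_ascii_field(con, 8)                           # header bytes
  readChar(con, 44, useBytes = TRUE)                 # reserved
  n_rec <- as.integer(read_ascii_field(con, 8))
  rec_dur <- as.numeric(read_ascii_field(con, 8))
  ns <- as.integer(read_ascii_field(con, 4))
  fld <- function(w) vapply(seq_len(ns), function(i) read_ascii_field(con, w), "")
  labels <- fld(16); fld(80)
  dims <- fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing sampling rates are not supported")
  srate <- spr[1] / rec_dur
  scale <- (pmax - pmin) / (dmax - dmin)
  offset <- pmin - scale * dmin
  # unit normalization to microvolts
  unit_mult <- ifelse(tolower(dims) %in% c("mv"), 1e3,
                      ifelse(tolower(dims) %in% c("v"), 1e6, 1))
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      x <- readBin(con, "integer", n = spr[1], size = 2L, signed = TRUE,
                   endian = "little")
      data[s, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (x * scale[s] + offset[s]) * unit_mult[s]
    }
  }
  eeg_recording(data, srate,
                data.frame(name = labels, type = "EEG", stringsAsFactors = FALSE))
}

#' Write a continuous EDF recording (16-bit, one-second records)
#'
#' Physical range is taken from the data with a small margin; quantization
#' to the 16-bit digital range is lossy (as in any EDF export).
#'
#' @param rec an `eeg_recording` with an integer number of samples per second
#' @param path output `.edf` path
#' @export
write_edf <- function(rec, path) {
  spr <- rec$srate
  if (abs(spr - round(spr)) > 1e-9) stop("EDF writer needs an integer sampling rate")
  spr <- as.integer(round(spr))
  ns_sig <- n_channels(rec)
  n_rec <- floor(ncol(rec$data) / spr)
  if (n_rec < 1L) stop("recording shorter than one EDF record")
  phys_max <- max(abs(rec$data), 1e-6) * 1.01
  phys_min <- -phys_max
  dmax <- 32767L; dmin <- -32768L
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns_sig
  writeChar(paste0(
    pad("0", 8), pad("synthetic subject", 80), pad("resteeg export", 80),
    pad("01.01.26", 8), pad("00.00.00", 8), pad(hdr_bytes, 8), pad("", 44),
    pad(n_rec, 8), pad("1", 8), pad(ns_sig, 4)), con, eos = NULL)
  wf <- function(vals, w) writeChar(paste(vapply(vals, pad, "", w = w), collapse = ""),
                                    con, eos = NULL)
  wf(rec$channels$name, 16); wf(rep("", ns_sig), 80)
  wf(rep("uV", ns_sig), 8)
  wf(rep(formatC(phys_min, format = "g", digits = 6), ns_sig), 8)
  wf(rep(formatC(phys_max, format = "g", digits = 6), ns_sig), 8)
  wf(rep(dmin, ns_sig), 8); wf(rep(dmax, ns_sig), 8)
  wf(rep("", ns_sig), 80); wf(rep(spr, ns_sig), 8); wf(rep("", ns_sig), 32)
  scale <- (dmax - dmin) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    sel <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns_sig)) {
      dig <- as.integer(round((rec$data[s, sel] - phys_min) * scale + dmin))
      writeBin(pmin(pmax(dig, dmin), dmax), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
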