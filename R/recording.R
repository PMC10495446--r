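# The continuous-recording container and channel bookkeeping.

#' Construct a continuous EEG recording
#'
#' The core container of the package: a channels x samples amplitude matrix
#' in microvolts plus the metadata the pipeline needs (sampling rate,
#' channel table with types and 3-D head-RAS positions in meters, reference
#' label, power-line frequency, events, and discontinuity boundaries).
#' Sample indexing is 0-based and segments are half-open `[start, end)`;
#' a boundary at index `b` means the signal is discontinuous between
#' samples `b - 1` and `b`.
#'
#' @param data channels x samples numeric matrix (microvolts)
#' @param srate sampling rate in Hz
#' @param channels data.frame with columns `name`, `type` (EEG/EOG/ECG/EMG/other),
#'   optional `x`,`y`,`z` positions (meters, head RAS; NA when unknown) and
#'   `status` ("good"/"bad")
#' @param reference reference label or "average"
#' @param line_freq power-line frequency in Hz (NA when unknown)
#' @param events data.frame with columns `sample` (0-based) and `label`
#' @param boundaries integer vector of 0-based discontinuity sample indices
#' @return an object of class `eeg_recording`
#' @export
eeg_recording <- function(data, srate, channels, reference = "average",
                          line_freq = NA_real_, events = NULL, boundaries = integer()) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("srate must be a single positive number")
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (!all(c("name", "type") %in% names(channels)))
    stop("channels must have 'name' and 'type' columns")
  if (anyDuplicated(channels$name)) stop("channel names must be unique")
  if (nrow(channels) != nrow(data))
    stop("data row count (", nrow(data), ") != channel count (", nrow(channels), ")")
  for (col in c("x", "y", "z")) if (is.null(channels[[col]])) channels[[col]] <- NA_real_
  if (is.null(channels$status)) channels$status <- "good"
  pos <- as.matrix(channels[, c("x", "y", "z")])
  if (any(!is.na(pos) & !is.finite(pos))) stop("channel positions must be finite when present")
  if (is.null(events)) events <- data.frame(sample = integer(), label = character())
  boundaries <- as.integer(sort(unique(boundaries)))
  if (length(boundaries) && (any(boundaries < 0L) || any(boundaries > ncol(data))))
    stop("boundary indices must lie within [0, n_samples]")
  structure(list(data = data, srate = srate, channels = channels,
                 reference = reference, line_freq = line_freq,
                 events = events, boundaries = boundaries),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  cat(sprintf("  types: %s\n", paste(sprintf("%s:%d", names(table(x$channels$type)),
                                             table(x$channels$type)), collapse = " ")))
  cat(sprintf("  reference: %s | line freq: %s Hz | boundaries: %d | events: %d\n",
              x$reference, format(x$line_freq), length(x$boundaries), nrow(x$events)))
  invisible(x)
}

#' Number of samples / channels / duration helpers
#' @param rec an `eeg_recording`
#' @rdname recording-accessors
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname recording-accessors
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname recording-accessors
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$srate

#' Indices of channels of a given type
#' @noRd
chan_idx <- function(rec, type = "EEG") which(rec$channels$type %in% type)

#' Positions matrix (channels x 3) for a subset of channels
#' @noRd
chan_positions <- function(rec, idx = seq_len(n_channels(rec))) {
  as.matrix(rec$channels[idx, c("x", "y", "z")])
}

#' Drop channels by name, keeping order of the remainder
#'
#' @param rec an `eeg_recording`
#' @param names channel names to remove
#' @return the reduced recording
#' @export
remove_channels <- function(rec, names) {
  keep <- !(rec$channels$name %in% names)
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channels <- rec$channels[keep, , drop = FALSE]
  rownames(rec$channels) <- NULL
  rec
}

#' Built-in standard 10-20/10-10 electrode montage (head RAS, meters)
#'
#' Positions are computed on a 9 cm sphere from the standard 10-20 arc
#' fractions (vertex angles and azimuths), with intermediate 10-10 sites as
#' spherical midpoints of their defining neighbours. Coordinates: +x right,
#' +y anterior, +z superior; sphere centered at the head origin.
#'
#' @param n_channels optionally return only the first `n_channels` rows
#' @return data.frame with columns name, type, x, y, z
#' @export
standard_montage <- function(n_channels = NULL) {
  r <- 0.09
  ang <- function(theta, az) {  # theta from vertex, az from nose, clockwise to right
    th <- theta * pi / 180; a <- az * pi / 180
    c(x = sin(th) * sin(a), y = sin(th) * cos(a), z = cos(th))
  }
  base <- list(
    Cz = ang(0, 0),
    Fz = ang(36, 0),    Pz = ang(36, 180),
    C3 = ang(36, -90),  C4 = ang(36, 90),
    Fpz = ang(72, 0),   Oz = ang(72, 180),
    Fp1 = ang(72, -18), Fp2 = ang(72, 18),
    F7 = ang(72, -54),  F8 = ang(72, 54),
    T7 = ang(72, -90),  T8 = ang(72, 90),
    P7 = ang(72, -126), P8 = ang(72, 126),
    O1 = ang(72, -162), O2 = ang(72, 162)
  )
  slerp <- function(p, q) { v <- (p + q) / 2; v / sqrt(sum(v^2)) }
  base$F3 <- slerp(base$Fz, base$F7); base$F4 <- slerp(base$Fz, base$F8)
  base$P3 <- slerp(base$Pz, base$P7); base$P4 <- slerp(base$Pz, base$P8)
  base$FC1 <- slerp(base$Fz, base$C3); base$FC2 <- slerp(base$Fz, base$C4)
  base$CP1 <- slerp(base$Pz, base$C3); base$CP2 <- slerp(base$Pz, base$C4)
  base$FC5 <- slerp(base$F7, base$C3); base$FC6 <- slerp(base$F8, base$C4)
  base$CP5 <- slerp(base$P7, base$C3); base$CP6 <- slerp(base$P8, base$C4)
  base$AFz <- slerp(base$Fpz, base$Fz); base$POz <- slerp(base$Oz, base$Pz)
  base$FCz <- slerp(base$Fz, base$Cz); base$CPz <- slerp(base$Pz, base$Cz)
  ord <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
           "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2", "Fpz",
           "Oz", "FC1", "FC2", "CP1", "CP2", "FC5", "FC6", "CP5", "CP6",
           "AFz", "POz", "CPz")
  pos <- t(vapply(base[ord], identity, numeric(3))) * r
  out <- data.frame(name = ord, type = "EEG",
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    stringsAsFactors = FALSE)
  if (!is.null(n_channels)) {
    if (n_channels > nrow(out))
      stop("built-in montage has only ", nrow(out), " positions")
    out <- out[seq_len(n_channels), ]
  }
  rownames(out) <- NULL
  out
}
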