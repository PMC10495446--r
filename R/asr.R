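# Stage 6: artifact-subspace bad-segment detection (removal variant).
# Calibration keeps windows in which under 7.5% of channels are noisy
# (robust RMS z > 5.5); detection flags 0.5-s windows whose variance along
# any calibration principal axis exceeds 20x the calibration variance.

#' Calibrate the artifact-subspace model on quasi-clean data
#'
#' Per-channel RMS is computed in sliding 1-s windows (50% overlap) and
#' z-scored robustly across windows; a window enters the calibration set if
#' the fraction of channels with z above `asr_rms_z` is below
#' `asr_calib_noisy_frac`. The model is the principal axes and per-axis
#' variances of the retained data.
#'
#' @param rec a cleaned, re-referenced `eeg_recording`
#' @param params an `eeg_params` list
#' @return an `asr_calibration`: `axes` (channels x channels), `variance`,
#'   `kept_windows`, `n_windows`, `channel_names`
#' @export
asr_calibrate <- function(rec, params = default_params()) {
  eeg <- chan_idx(rec, "EEG")
  X <- rec$data[eeg, , drop = FALSE]
  srate <- rec$srate
  w <- max(2L, round(1 * srate))
  step <- max(1L, floor(w / 2))
  starts <- seq(0L, ncol(X) - w, by = step)
  if (!length(starts)) stop("recording too short for ASR calibration")
  rms <- vapply(starts, function(s)
    sqrt(rowMeans(X[, (s + 1L):(s + w), drop = FALSE]^2)), numeric(nrow(X)))
  # rms: channels x windows; robust z across windows, per channel
  z <- rms
  for (i in seq_len(nrow(rms))) {
    md <- stats::median(rms[i, ]); s <- stats::mad(rms[i, ])
    z[i, ] <- if (s < 1e-12) 0 else (rms[i, ] - md) / s
  }
  noisy_frac <- colMeans(z > params$asr_rms_z)
  keep <- noisy_frac < params$asr_calib_noisy_frac
  kept_s <- sum(keep) * w / 2 / srate + w / 2 / srate
  if (sum(keep) < 1 || kept_s < 5)
    stop("under 5 s of calibration data survive; record a longer or cleaner session")
  sel <- unique(unlist(lapply(starts[keep], function(s) (s + 1L):(s + w))))
  Xc <- X[, sel, drop = FALSE]
  Xc <- Xc - rowMeans(Xc)
  C <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  structure(list(axes = e$vectors, variance = pmax(e$values, 1e-15),
                 kept_windows = which(keep), n_windows = length(starts),
                 channel_names = rec$channels$name[eeg]),
            class = "asr_calibration")
}

#' Flag artifactual time segments against an ASR calibration
#'
#' Sliding 0.5-s windows (50% overlap) are projected onto the calibration
#' axes; a window is flagged when the variance along any axis exceeds
#' `asr_cutoff` (default 20) times the calibration variance on that axis.
#' Flagged windows are merged into a per-sample boolean mask.
#'
#' @param rec the recording to scan
#' @param calib an `asr_calibration`
#' @param params an `eeg_params` list
#' @return a `segment_mask`: logical per-sample vector (`TRUE` = bad) with
#'   merged bad intervals as an attribute-free list component
#' @export
asr_flag_segments <- function(rec, calib, params = default_params()) {
  eeg <- match(calib$channel_names, rec$channels$name)
  if (anyNA(eeg)) stop("channel-order mismatch between recording and calibration")
  X <- rec$data[eeg, , drop = FALSE]
  srate <- rec$srate
  ns <- ncol(X)
  w <- max(2L, round(0.5 * srate))
  step <- max(1L, floor(w / 2))
  starts <- unique(c(seq(0L, ns - w, by = step), ns - w))
  mask <- logical(ns)
  A <- t(calib$axes)                      # axes in rows
  for (s in starts) {
    seg <- X[, (s + 1L):(s + w), drop = FALSE]
    seg <- seg - rowMeans(seg)
    P <- A %*% seg
    v <- rowMeans(P^2)
    if (any(v > params$asr_cutoff * calib$variance))
      mask[(s + 1L):(s + w)] <- TRUE
  }
  segment_mask(mask)
}

#' Build a segment mask object from a logical vector
#' @param mask logical per-sample vector, TRUE = bad
#' @return object of class `segment_mask` with merged `intervals`
#'   (0-based, half-open) and the vector itself
#' @export
segment_mask <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  iv <- cbind(start = starts[r$values], end = ends[r$values])
  structure(list(mask = mask, intervals = iv), class = "segment_mask")
}

#' @export
print.segment_mask <- function(x, ...) {
  cat(sprintf("<segment_mask> %d/%d samples bad (%.1f%%) in %d interval(s)\n",
              sum(x$mask), length(x$mask), 100 * mean(x$mask), nrow(x$intervals)))
  invisible(x)
}

#' Excise bad segments from a recording, inserting boundaries at the cuts
#'
#' @param rec an `eeg_recording`
#' @param mask a `segment_mask` of matching length
#' @return the shortened recording; each cut becomes a boundary index and
#'   events/boundaries are remapped onto the new time base (events inside
#'   removed spans are dropped)
#' @export
excise_segments <- function(rec, mask) {
  m <- mask$mask
  if (length(m) != n_samples(rec)) stop("mask length != number of samples")
  if (!any(m)) return(rec)
  keep <- !m
  new_index <- cumsum(keep) - 1L           # 0-based new index of kept samples
  rec$data <- rec$data[, keep, drop = FALSE]
  # boundaries: old boundaries surviving + one per cut
  old_b <- rec$boundaries
  old_b <- old_b[old_b > 0 & old_b <= length(m)]
  b1 <- vapply(old_b, function(i) sum(keep[seq_len(i)]), integer(1))
  cuts <- mask$intervals[, "end"]
  b2 <- vapply(cuts, function(i) sum(keep[seq_len(i)]), integer(1))
  nb <- sort(unique(c(b1, b2)))
  nb <- nb[nb > 0L & nb < sum(keep)]
  rec$boundaries <- as.integer(nb)
  if (nrow(rec$events)) {
    ev_keep <- keep[rec$events$sample + 1L]
    rec$events <- rec$events[ev_keep, , drop = FALSE]
    rec$events$sample <- new_index[rec$events$sample + 1L]
  }
  rec
}
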