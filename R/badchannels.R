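# Stage 2b: automatic bad-channel detection.
# Three criteria: (1) flat for a contiguous run longer than `flat_max_s`;
# (2) robust z-score of the noise-to-signal ratio above `noise_z_thresh`;
# (3) the channel cannot be predicted from random subsets of the other
# channels for at least `predictability_frac` of the recording.

#' Detect artifactual channels
#'
#' Applies the three rejection criteria to the EEG channels of a
#' high-passed recording and returns a per-channel report. The
#' noise-to-signal ratio is sd(content above 40 Hz) / sd(content below
#' 40 Hz), z-scored robustly (median / 1.4826 MAD) across channels. The
#' predictability criterion interpolates each channel from `pred_n_subsets`
#' random subsets of 25% of the other channels via spherical splines and
#' asks for a windowed correlation of at least `pred_corr_thresh` in a
#' fraction `predictability_frac` of 5-s windows. Subset draws are seeded
#' from `params$seeds$badchan`.
#'
#' @param rec a high-passed `eeg_recording`
#' @param params an `eeg_params` list
#' @param raw optional pre-filter recording: the flat-run criterion is
#'   evaluated on it when given, since zero-phase high-pass filtering
#'   smears low-frequency content into a flat span and destroys exact
#'   flatness (amplifier flatlines are a property of the raw signal)
#' @return an object of class `bad_channel_report`: data.frame of flags per
#'   EEG channel plus `removed` (names)
#' @export
detect_bad_channels <- function(rec, params = default_params(), raw = NULL) {
  eeg <- chan_idx(rec, "EEG")
  nch <- length(eeg)
  names_eeg <- rec$channels$name[eeg]
  srate <- rec$srate
  X <- rec$data[eeg, , drop = FALSE]
  ns <- ncol(X)

  # criterion 1: flat run (on the raw signal when available)
  Xflat <- if (is.null(raw)) X else
    raw$data[match(names_eeg, raw$channels$name), , drop = FALSE]
  flat_run <- round(params$flat_max_s * srate)
  flat <- logical(nch)
  for (i in seq_len(nch)) {
    small <- c(abs(diff(Xflat[i, ])) < 1e-8, FALSE)
    r <- rle(small)
    flat[i] <- any(r$values & r$lengths > flat_run)
  }

  # criterion 2: robust z of noise-to-signal ratio
  split_hz <- min(40, srate / 2 * 0.8)
  hk <- fir_highpass_kernel(split_hz, trans_hz = split_hz / 4, srate = srate)
  hi <- fir_filter_matrix(X, hk)
  lo <- X - hi
  nsr <- apply(hi, 1, stats::sd) / pmax(apply(lo, 1, stats::sd), 1e-12)
  md <- stats::median(nsr); s <- stats::mad(nsr)
  z <- if (s < 1e-12) rep(0, nch) else (nsr - md) / s
  noisy <- z > params$noise_z_thresh

  # criterion 3: predictability from random channel subsets
  unpredictable <- logical(nch)
  pos_ok <- !is.na(rec$channels$x[eeg])
  cand <- which(!flat & !noisy)
  if (sum(pos_ok[cand]) >= 8) {
    win <- round(params$pred_window_s * srate)
    n_win <- floor(ns / win)
    use <- seq_len(n_win * win)
    pred_src <- cand[pos_ok[cand]]
    unpredictable <- with_seed(params$seeds$badchan %||% 3000L, {
      out <- logical(nch)
      for (i in which(pos_ok)) {
        others <- setdiff(pred_src, i)
        # 25% of the other channels, floored at 10: the spline field is
        # dominated by spherical harmonics up to degree ~3 (>= 9 basis
        # functions), so prediction from fewer electrodes is
        # under-determined on sparse (~20-electrode) montages
        k <- min(length(others),
                 max(10L, round(params$pred_subset_frac * length(others))))
        tgt_w <- matrix(X[i, use], win)
        tgt_c <- sweep(tgt_w, 2, colMeans(tgt_w))
        tgt_ss <- sqrt(colSums(tgt_c^2))
        best <- rep(-1, n_win)
        for (rset in seq_len(params$pred_n_subsets)) {
          sub <- sample(others, k)
          Tm <- spline_interp_matrix(chan_positions(rec, eeg[sub]),
                                     chan_positions(rec, eeg[i]))
          pred <- as.vector(Tm %*% X[sub, use, drop = FALSE])
          pw <- matrix(pred, win)
          pc <- sweep(pw, 2, colMeans(pw))
          cc <- colSums(pc * tgt_c) / pmax(sqrt(colSums(pc^2)) * tgt_ss, 1e-12)
          best <- pmax(best, cc)
        }
        out[i] <- mean(best >= params$pred_corr_thresh) < params$predictability_frac
      }
      out
    })
  }

  report <- data.frame(name = names_eeg, flat = flat, noisy = noisy,
                       unpredictable = unpredictable,
                       stringsAsFactors = FALSE)
  removed <- names_eeg[flat | noisy | unpredictable]
  if (nch - length(removed) < 8)
    stop("fewer than 8 good EEG channels remain (", nch - length(removed),
         "); the prediction criterion is meaningless at this channel count")
  structure(list(report = report, removed = removed), class = "bad_channel_report")
}

#' @export
print.bad_channel_report <- function(x, ...) {
  cat(sprintf("<bad_channel_report> %d/%d channels flagged: %s\n",
              length(x$removed), nrow(x$report),
              if (length(x$removed)) paste(x$removed, collapse = ", ") else "none"))
  invisible(x)
}

#' Remove the channels flagged in a bad-channel report
#' @param rec an `eeg_recording`
#' @param report a `bad_channel_report`
#' @return the reduced recording
#' @export
apply_bad_channels <- function(rec, report) {
  if (!length(report$removed)) return(rec)
  remove_channels(rec, report$removed)
}

#' Evaluate an expression with a local RNG seed, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}
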