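# Preprocessing stages 0-3: optional downsampling, adaptive line-noise
# regression, high-pass filtering, average re-referencing.

#' Downsample a recording after anti-alias filtering
#'
#' A zero-phase FIR low-pass at 45% of the target rate is applied before
#' the signal is re-evaluated on the coarser grid; events and boundaries
#' are remapped proportionally. Output length is `floor(n * target / srate)`.
#'
#' @param rec an `eeg_recording`
#' @param target_hz new sampling rate, must be below the native rate
#' @return the resampled recording
#' @export
resample_recording <- function(rec, target_hz) {
  if (target_hz >= rec$srate)
    stop("target rate (", target_hz, ") must be below the native rate (", rec$srate, ")")
  ratio <- target_hz / rec$srate
  n_out <- floor(n_samples(rec) * ratio)
  h <- fir_lowpass_kernel(fir_order(0.1 * target_hz, rec$srate, max_order = 4001L),
                          0.45 * target_hz, rec$srate)
  filt <- fir_filter_matrix(rec$data, h)
  # sample the filtered signal at the new grid (linear interpolation)
  t_new <- (seq_len(n_out) - 1L) / ratio          # position in old samples, 0-based
  i0 <- pmin(floor(t_new), n_samples(rec) - 2L)
  frac <- t_new - i0
  out <- filt[, i0 + 1L, drop = FALSE] * rep(1 - frac, each = nrow(filt)) +
         filt[, i0 + 2L, drop = FALSE] * rep(frac, each = nrow(filt))
  rec$data <- out
  rec$srate <- target_hz
  rec$events$sample <- as.integer(round(rec$events$sample * ratio))
  rec$boundaries <- as.integer(unique(pmin(round(rec$boundaries * ratio), n_out)))
  rec
}

#' Remove power-line noise by windowed sinusoidal regression
#'
#' In sliding windows (default 4 s, 50% overlap) a sine/cosine pair at the
#' line frequency and each harmonic below Nyquist is regressed out of every
#' channel. A harmonic is subtracted only where its regression F-statistic
#' is significant, so broadband content is preserved and no spectral notch
#' is created; window estimates are Hann-crossfaded, which tracks slowly
#' drifting line amplitude.
#'
#' @param rec an `eeg_recording` with `line_freq` set
#' @param window_s regression window length in seconds
#' @param p_crit significance level for subtracting a harmonic
#' @return the cleaned recording
#' @export
remove_line_noise <- function(rec, window_s = 4, p_crit = 1e-3) {
  if (is.na(rec$line_freq) || is.null(rec$line_freq))
    stop("line_freq is not set; specify the power-line frequency in the ",
         "*_eeg.json sidecar (e.g. 50 or 60 Hz)")
  ns <- n_samples(rec); nch <- n_channels(rec); srate <- rec$srate
  harmonics <- rec$line_freq * seq_len(floor((srate / 2 - 1) / rec$line_freq))
  if (!length(harmonics)) return(rec)
  w <- min(ns, round(window_s * srate))
  step <- max(1L, floor(w / 2))
  starts <- unique(c(seq(0L, ns - w, by = step), ns - w))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  acc <- matrix(0, nch, ns); wt <- numeric(ns)
  nh <- length(harmonics)
  fcrit <- stats::qf(1 - p_crit, 2, w - 2 * nh - 1)
  for (s in starts) {
    idx <- (s + 1L):(s + w)
    tt <- (idx - 1L) / srate
    X <- do.call(cbind, lapply(harmonics, function(f)
      cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))))
    Y <- t(rec$data[, idx, drop = FALSE])        # w x nch
    Yc <- sweep(Y, 2, colMeans(Y))
    B <- solve(crossprod(X), crossprod(X, Yc))   # 2nh x nch
    fit_all <- X %*% B
    rss <- colSums((Yc - fit_all)^2)
    est <- matrix(0, w, nch)
    for (hi in seq_len(nh)) {
      cols <- (2 * hi - 1L):(2 * hi)
      comp <- X[, cols, drop = FALSE] %*% B[cols, , drop = FALSE]
      ssh <- colSums(comp^2)
      fstat <- (ssh / 2) / (rss / (w - 2 * nh - 1))
      sig <- !is.na(fstat) & fstat > fcrit   # flat windows give 0/0
      if (any(sig)) est[, sig] <- est[, sig] + comp[, sig, drop = FALSE]
    }
    acc[, idx] <- acc[, idx] + t(est * hann)
    wt[idx] <- wt[idx] + hann
  }
  wt[wt == 0] <- 1
  rec$data <- rec$data - sweep(acc, 2, wt, "/")
  rec
}

#' Zero-phase FIR high-pass filter
#'
#' Hamming windowed-sinc design with -6 dB at the transition-band center
#' (default 0.5 Hz, transition 0.25-0.75 Hz); removes DC and slow drifts.
#'
#' @param rec an `eeg_recording`
#' @param params an `eeg_params` list (uses `hp_transition_band`)
#' @return the filtered recording
#' @export
highpass_filter <- function(rec, params = default_params()) {
  tb <- params$hp_transition_band
  if (rec$srate <= 2) stop("sampling rate too low for high-pass filtering")
  h <- fir_highpass_kernel(cutoff_hz = mean(tb), trans_hz = diff(tb),
                           srate = rec$srate, max_order = 20001L)
  rec$data <- fir_filter_matrix(rec$data, h)
  rec
}

#' Re-reference EEG channels to the common average
#'
#' Subtracts the instantaneous mean over EEG channels from every EEG
#' channel. Optionally the time course of the original reference electrode
#' (the negated pre-re-reference mean) is reconstructed and appended as a
#' new channel named after `rec$reference`.
#'
#' @param rec an `eeg_recording`
#' @param add_back_ref append the reconstructed original reference channel?
#' @return the re-referenced recording, `reference` set to "average"
#' @export
rereference_average <- function(rec, add_back_ref = FALSE) {
  eeg <- chan_idx(rec, "EEG")
  if (length(eeg) < 2) stop("average reference needs at least 2 EEG channels")
  mu <- colMeans(rec$data[eeg, , drop = FALSE])
  rec$data[eeg, ] <- sweep(rec$data[eeg, , drop = FALSE], 2, mu)
  if (add_back_ref && !identical(rec$reference, "average")) {
    ref_name <- rec$reference
    std <- standard_montage()
    m <- match(ref_name, std$name)
    newch <- data.frame(name = ref_name, type = "EEG",
                        x = if (is.na(m)) NA_real_ else std$x[m],
                        y = if (is.na(m)) NA_real_ else std$y[m],
                        z = if (is.na(m)) NA_real_ else std$z[m],
                        status = "good", stringsAsFactors = FALSE)
    rec$data <- rbind(rec$data, -mu)
    rec$channels <- rbind(rec$channels, newch)
    rownames(rec$channels) <- NULL
  }
  rec$reference <- "average"
  rec
}
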