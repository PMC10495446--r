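# Stage 4-6 stabilization and stage 7 epoching.
# ICA rotations are not deterministic across initializations, and small
# differences propagate into the bad-segment mask, so stages 4-6 are run
# n_ica_repetitions times (seeds base+1..base+n) and the repetition whose
# mask is closest (L1) to the per-sample mean mask is kept.

#' Run ICA cleaning, interpolation and segment flagging with mask stabilization
#'
#' For each repetition r: fit ICA with seed `seeds$ica + r`, classify and
#' subtract artifactual ICs, interpolate the removed channels, calibrate
#' ASR and flag bad segments. The repetition whose mask minimizes the L1
#' distance to the mean mask over repetitions (ties: lowest repetition
#' index) is selected; its flagged intervals are excised from the data with
#' boundaries at each cut.
#'
#' @param rec recording after stages 1-3 (line noise, high-pass + bad
#'   channel removal, average reference)
#' @param params an `eeg_params` list
#' @param report the `bad_channel_report` from stage 2 (for interpolation)
#' @param original_channels channel table before bad-channel removal
#' @return list: `rec` (cleaned continuous recording with cuts as
#'   boundaries), `mask` (selected `segment_mask` on the pre-excision time
#'   base), `diagnostics` (per-repetition summary, selected index, removed
#'   IC bookkeeping)
#' @export
stabilize_and_clean <- function(rec, params = default_params(),
                                report = NULL, original_channels = NULL) {
  n_rep <- params$n_ica_repetitions
  base_seed <- params$seeds$ica %||% 1000L
  if (is.null(report)) report <- list(removed = character())
  if (is.null(original_channels)) original_channels <- rec$channels
  masks <- matrix(FALSE, n_rep, n_samples(rec))
  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    res <- tryCatch({
      dec <- fit_ica(rec, seed = as.integer(base_seed + r))
      cls <- classify_ics(dec, rec)
      rj <- reject_ics(rec, dec, cls, params)
      rec_i <- interpolate_channels(rj$rec, report, original_channels)
      calib <- asr_calibrate(rec_i, params)
      mask <- asr_flag_segments(rec_i, calib, params)
      list(rec = rec_i, mask = mask, removed_ics = rj$removed,
           ic_probs = rj$probabilities)
    }, error = function(e)
      stop("repetition ", r, " of ", n_rep, " failed: ", conditionMessage(e)))
    masks[r, ] <- res$mask$mask
    reps[[r]] <- res
  }
  mean_mask <- colMeans(masks)
  d <- rowSums(abs(sweep(masks, 2, mean_mask)))
  sel <- which.min(d)                       # which.min takes the first tie
  chosen <- reps[[sel]]
  cleaned <- excise_segments(chosen$rec, chosen$mask)
  diagnostics <- list(
    selected = sel,
    l1_to_mean = d,
    rejected_fraction = rowMeans(masks),
    removed_ics = chosen$removed_ics,
    ic_probabilities = chosen$ic_probs,
    interpolated = report$removed
  )
  list(rec = cleaned, mask = chosen$mask, diagnostics = diagnostics)
}

#' Cut continuous data into fixed-length overlapping epochs
#'
#' Epoch starts are spaced `epoch_len_s * (1 - epoch_overlap)` seconds
#' apart; a candidate epoch `[s, s+L)` is rejected when a discontinuity
#' boundary falls strictly inside it (`s < b < s+L`).
#'
#' @param rec an `eeg_recording`
#' @param params an `eeg_params` list
#' @return an `eeg_epochs` object: `data` (epochs x channels x samples),
#'   `srate`, `channels`, `starts` (0-based start samples), `epoch_len_s`,
#'   `overlap`
#' @export
epoch_data <- function(rec, params = default_params()) {
  L <- params$epoch_len_s * rec$srate
  if (abs(L - round(L)) > 1e-9)
    stop("epoch_len_s * srate must be an integer number of samples")
  L <- as.integer(round(L))
  step <- max(1L, as.integer(round(L * (1 - params$epoch_overlap))))
  ns <- n_samples(rec)
  if (ns < L) stop("zero epochs: recording shorter than one epoch")
  starts <- seq(0L, ns - L, by = step)
  ok <- vapply(starts, function(s)
    !any(rec$boundaries > s & rec$boundaries < s + L), logical(1))
  starts <- starts[ok]
  if (!length(starts)) stop("zero epochs remain after boundary rejection")
  arr <- array(0, dim = c(length(starts), n_channels(rec), L))
  for (i in seq_along(starts))
    arr[i, , ] <- rec$data[, (starts[i] + 1L):(starts[i] + L), drop = FALSE]
  structure(list(data = arr, srate = rec$srate, channels = rec$channels,
                 starts = starts, epoch_len_s = params$epoch_len_s,
                 overlap = params$epoch_overlap),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g s, %.0f%% overlap)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$epoch_len_s, 100 * x$overlap))
  invisible(x)
}

#' Number of epochs
#' @param epochs an `eeg_epochs`
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]

#' Band-pass filter every epoch (zero-phase FIR, reflect-padded)
#'
#' @param epochs an `eeg_epochs`
#' @param band numeric `c(lo, hi)` in Hz
#' @return filtered `eeg_epochs`
#' @export
filter_epochs <- function(epochs, band) {
  L <- dim(epochs$data)[3]
  srate <- epochs$srate
  trans <- max(min(2, band[1] / 2), 0.5)
  h <- fir_bandpass_kernel(band[1], band[2], trans, srate, max_order = 2L * L - 1L)
  for (e in seq_len(dim(epochs$data)[1]))
    epochs$data[e, , ] <- fir_filter_matrix(epochs$data[e, , , drop = TRUE], h)
  epochs
}

#' The full seven-stage preprocessing chain on one recording
#'
#' Runs optional downsampling, line-noise removal, high-pass filtering,
#' bad-channel detection and removal, average re-referencing, the
#' repetition-stabilized ICA + interpolation + segment-removal block, and
#' epoching, collecting a run log along the way.
#'
#' @param rec a raw `eeg_recording`
#' @param params an `eeg_params` list
#' @param add_back_ref reconstruct and append the original reference channel?
#' @return list: `epochs` (`eeg_epochs`), `rec` (cleaned continuous),
#'   `runlog` (stage counts and the three summary fractions)
#' @export
preprocess_recording <- function(rec, params = default_params(), add_back_ref = FALSE) {
  t0 <- Sys.time()
  n_chan0 <- sum(rec$channels$type == "EEG")
  dur0 <- duration_s(rec)
  if (!is.null(params$downsample_hz) && params$downsample_hz < rec$srate)
    rec <- resample_recording(rec, params$downsample_hz)
  rec <- remove_line_noise(rec)
  raw <- rec
  rec <- highpass_filter(rec, params)
  report <- detect_bad_channels(rec, params, raw = raw)
  original_channels <- rec$channels
  rec <- apply_bad_channels(rec, report)
  rec <- rereference_average(rec, add_back_ref = add_back_ref)
  st <- stabilize_and_clean(rec, params, report, original_channels)
  epochs <- epoch_data(st$rec, params)
  runlog <- list(
    n_channels_total = n_chan0,
    rejected_channels = report$removed,
    n_rejected_channels = length(report$removed),
    frac_rejected_channels = length(report$removed) / max(n_chan0, 1),
    removed_ics = st$diagnostics$removed_ics,
    n_removed_ics = length(st$diagnostics$removed_ics),
    bad_segment_s = sum(st$mask$mask) / rec$srate,
    frac_bad_segments = mean(st$mask$mask),
    duration_in_s = dur0,
    n_epochs = n_epochs(epochs),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  list(epochs = epochs, rec = st$rec, runlog = runlog,
       bad_channel_report = report, mask = st$mask)
}
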