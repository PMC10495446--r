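# Pipeline parameters: defaults, JSON loading, validation.

#' Default pipeline parameters
#'
#' Returns the full parameter set with the pipeline's published defaults:
#' channels are flagged flat after 5 s, the noise z-score threshold is 4,
#' channels must be predictable 80% of the time, ICs with P(Muscle) or
#' P(Eye) above 0.8 are subtracted, the ICA/segment-mask procedure is
#' repeated 10 times, ASR calibration keeps windows with under 7.5% noisy
#' channels (RMS z > 5.5) and flags segments exceeding 20x calibration
#' variance, data are cut into 2-s epochs with 50% overlap, frequency bands
#' are theta 4-7.9, alpha 8-12.9, beta 13-30, gamma 30.1-80 Hz, epochs are
#' zero-padded to 10 s (0.1 Hz spectral grid), the LCMV regularization is
#' 5% and graphs keep the 20% strongest connections.
#'
#' @return a named list of class `eeg_params`
#' @export
default_params <- function() {
  structure(list(
    downsample_hz = NULL,
    hp_transition_band = c(0.25, 0.75),
    flat_max_s = 5,
    noise_z_thresh = 4,
    predictability_frac = 0.8,
    pred_corr_thresh = 0.8,
    pred_window_s = 5,
    pred_n_subsets = 50,
    pred_subset_frac = 0.25,
    ic_reject_classes = c("Muscle", "Eye"),
    ic_reject_prob = 0.8,
    n_ica_repetitions = 10,
    asr_calib_noisy_frac = 0.075,
    asr_rms_z = 5.5,
    asr_cutoff = 20,
    epoch_len_s = 2,
    epoch_overlap = 0.5,
    bands = list(theta = c(4, 7.9), alpha = c(8, 12.9),
                 beta = c(13, 30), gamma = c(30.1, 80)),
    pad_to_s = 10,
    lcmv_reg = 0.05,
    atlas = "atlas100-synthetic",
    graph_density = 0.2,
    n_null = 10,
    seeds = list(ica = 1000L, graph = 2000L)
  ), class = "eeg_params")
}

#' Load parameters from a JSON file
#'
#' Unspecified fields take the defaults of [default_params()]; the merged
#' set is validated. An empty JSON object therefore yields the full default
#' parameter set.
#'
#' @param path path to a JSON parameter file
#' @return validated `eeg_params` list
#' @export
load_params <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_params(user)
}

#' Merge a partial parameter list onto the defaults and validate
#' @param user named list of overrides (possibly empty)
#' @return validated `eeg_params`
#' @export
merge_params <- function(user = list()) {
  p <- default_params()
  if (length(user)) {
    unknown <- setdiff(names(user), names(p))
    if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    for (nm in names(user)) {
      v <- user[[nm]]
      if (nm == "bands") v <- lapply(v, as.numeric)
      if (nm == "seeds") v <- utils::modifyList(p$seeds, as.list(v))
      p[[nm]] <- v
    }
  }
  validate_params(p)
  p
}

#' Validate a parameter set, stopping with the offending field name
#' @noRd
validate_params <- function(p) {
  pos_fields <- c("flat_max_s", "noise_z_thresh", "predictability_frac",
                  "pred_corr_thresh", "pred_window_s", "pred_n_subsets",
                  "pred_subset_frac", "ic_reject_prob", "n_ica_repetitions",
                  "asr_calib_noisy_frac", "asr_rms_z", "asr_cutoff",
                  "epoch_len_s", "pad_to_s", "lcmv_reg", "n_null")
  for (f in pos_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", f, "' must be a single strictly positive number")
  }
  if (!is.null(p$downsample_hz) &&
      (!is.numeric(p$downsample_hz) || p$downsample_hz <= 0))
    stop("parameter 'downsample_hz' must be positive when set")
  if (length(p$hp_transition_band) != 2L || any(p$hp_transition_band <= 0) ||
      diff(p$hp_transition_band) <= 0)
    stop("parameter 'hp_transition_band' must be an increasing positive pair")
  if (p$graph_density <= 0 || p$graph_density >= 1)
    stop("parameter 'graph_density' must lie strictly between 0 and 1")
  if (p$epoch_overlap <= 0 || p$epoch_overlap >= 1)
    stop("parameter 'epoch_overlap' must lie strictly between 0 and 1")
  if (p$ic_reject_prob >= 1) stop("parameter 'ic_reject_prob' must be below 1")
  b <- p$bands
  if (!length(b) || is.null(names(b))) stop("parameter 'bands' must be a named list")
  edges <- t(vapply(b, function(v) as.numeric(v[1:2]), numeric(2)))
  if (any(edges[, 2] <= edges[, 1])) stop("parameter 'bands' intervals must be ascending")
  o <- order(edges[, 1])
  if (any(edges[o, 1][-1] < edges[o, 2][-nrow(edges)]))
    stop("parameter 'bands' intervals must not overlap")
  invisible(TRUE)
}

#' Write the resolved parameter set to JSON (reproducibility dump)
#' @param p an `eeg_params` list
#' @param path output JSON path
#' @export
write_params <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
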