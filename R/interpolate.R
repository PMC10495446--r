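# Stage 5: spherical-spline reconstruction of removed channels, restoring
# the original channel count and order.

#' Interpolate previously removed channels
#'
#' Reconstructs the channels listed in the bad-channel report by
#' spherical-spline interpolation (order 4) from the remaining EEG
#' channels, re-inserting them at their original positions so the output
#' channel order equals `original_channels`.
#'
#' @param rec the recording after bad channels were removed
#' @param report a `bad_channel_report`
#' @param original_channels the channel table before removal (with positions)
#' @return recording with the full original channel set
#' @export
interpolate_channels <- function(rec, report, original_channels) {
  bad <- report$removed
  if (!length(bad)) return(rec)
  orig <- as.data.frame(original_channels, stringsAsFactors = FALSE)
  miss <- setdiff(bad, orig$name)
  if (length(miss)) stop("original channel table lacks: ", paste(miss, collapse = ", "))
  bad_rows <- orig[match(bad, orig$name), ]
  if (any(is.na(bad_rows$x)))
    stop("missing electrode positions for interpolation of: ",
         paste(bad_rows$name[is.na(bad_rows$x)], collapse = ", "))
  good_eeg <- chan_idx(rec, "EEG")
  good_eeg <- good_eeg[!is.na(rec$channels$x[good_eeg])]
  if (length(good_eeg) < 4) stop("too few positioned EEG channels to interpolate from")
  Tm <- spline_interp_matrix(chan_positions(rec, good_eeg),
                             as.matrix(bad_rows[, c("x", "y", "z")]))
  recon <- Tm %*% rec$data[good_eeg, , drop = FALSE]

  # assemble in original order; channels absent from `orig` (e.g. an added
  # reference) are appended at the end in current order
  all_names <- c(orig$name, setdiff(rec$channels$name, orig$name))
  data_out <- matrix(0, length(all_names), ncol(rec$data))
  chan_out <- NULL
  for (j in seq_along(all_names)) {
    nm <- all_names[j]
    if (nm %in% rec$channels$name) {
      i <- match(nm, rec$channels$name)
      data_out[j, ] <- rec$data[i, ]
      chan_out <- rbind(chan_out, rec$channels[i, ])
    } else {
      i <- match(nm, bad)
      data_out[j, ] <- recon[i, ]
      row <- bad_rows[i, ]
      if (is.null(row$status)) row$status <- "good"
      row$status <- "good"
      chan_out <- rbind(chan_out, row[, c("name", "type", "x", "y", "z", "status")])
    }
  }
  rownames(chan_out) <- NULL
  rec$data <- data_out
  rec$channels <- chan_out
  rec
}
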