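# Feature stage 3: band-specific array-gain LCMV beamforming onto the
# atlas ROI centroids, with fixed orientation at the direction of maximum
# variance and 5% regularization of the sensor covariance.

#' Fit band-specific LCMV spatial filters
#'
#' The sensor covariance is averaged over (band-pass filtered) epochs and
#' regularized as `C + reg * (trace(C)/n) * I`. Array-gain convention:
#' each ROI's channels x 3 gain matrix is normalized to unit Frobenius
#' norm before the filter is built, which equalizes noise amplification
#' across ROIs of unequal sensitivity (otherwise weak-gain locations
#' dominate source power through blown-up weights). Per ROI, the
#' free-orientation filter `W3 = (L' C^-1 L)^-1 L' C^-1` is computed on
#' the normalized gain and the orientation fixed to the dominant
#' eigenvector of `W3 C W3'` (the direction of maximum output variance;
#' sign fixed by making its first nonzero component positive). The final
#' one-dimensional filter satisfies the unit-gain constraint
#' `w %*% (L_normalized %*% ori) == 1`.
#'
#' @param epochs band-pass-filtered `eeg_epochs`
#' @param lf a `lead_field`
#' @param band numeric `c(lo, hi)` in Hz (recorded on the result)
#' @param params an `eeg_params` list (uses `lcmv_reg`)
#' @return a `spatial_filters`: `weights` (ROI x channels), `orientation`
#'   (ROI x 3, unit rows), `band`, `channel_names`, `reg`
#' @export
lcmv_fit <- function(epochs, lf, band, params = default_params()) {
  idx <- match(lf$channel_names, epochs$channels$name)
  if (anyNA(idx))
    stop("lead field channels missing from epochs: ",
         paste(lf$channel_names[is.na(idx)], collapse = ", "))
  ne <- n_epochs(epochs)
  nch <- length(idx)
  C <- matrix(0, nch, nch)
  for (e in seq_len(ne)) {
    X <- epochs$data[e, idx, , drop = TRUE]
    X <- X - rowMeans(X)
    C <- C + tcrossprod(X) / ncol(X)
  }
  C <- C / ne
  Creg <- C + params$lcmv_reg * (sum(diag(C)) / nch) * diag(nch)
  Ci <- tryCatch(solve(Creg), error = function(e)
    stop("regularized covariance is singular: ", conditionMessage(e)))
  nroi <- dim(lf$gain)[1]
  W <- matrix(0, nroi, nch)
  ori <- matrix(0, nroi, 3)
  for (q in seq_len(nroi)) {
    L <- matrix(lf$gain[q, , ], ncol = 3)         # nch x 3
    L <- L / sqrt(sum(L^2))                       # array-gain normalization
    CiL <- Ci %*% L
    W3 <- solve(crossprod(L, CiL), t(CiL))        # 3 x nch
    M <- W3 %*% C %*% t(W3)
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
    u <- ev$vectors[, 1]
    nz <- which(abs(u) > 1e-12)[1]
    if (u[nz] < 0) u <- -u
    ori[q, ] <- u
    W[q, ] <- as.vector(crossprod(u, W3))
  }
  structure(list(weights = W, orientation = ori, band = band,
                 channel_names = lf$channel_names, reg = params$lcmv_reg,
                 roi_names = lf$atlas$roi_name),
            class = "spatial_filters")
}

#' @export
print.spatial_filters <- function(x, ...) {
  cat(sprintf("<spatial_filters> %d ROIs x %d channels, band %.1f-%.1f Hz, reg %.0f%%\n",
              nrow(x$weights), ncol(x$weights), x$band[1], x$band[2], 100 * x$reg))
  invisible(x)
}

#' Reconstruct virtual ROI time series
#'
#' Projects each (band-pass filtered) epoch through the per-ROI spatial
#' filters.
#'
#' @param epochs band-pass-filtered `eeg_epochs` (same band as `filters`)
#' @param filters a `spatial_filters`
#' @return a `virtual_ts`: `data` (epochs x ROI x samples), `srate`,
#'   `band`, `roi_names`
#' @export
virtual_timeseries <- function(epochs, filters) {
  idx <- match(filters$channel_names, epochs$channels$name)
  if (anyNA(idx)) stop("channel-order mismatch between filters and epochs")
  ne <- n_epochs(epochs)
  nroi <- nrow(filters$weights)
  L <- dim(epochs$data)[3]
  out <- array(0, dim = c(ne, nroi, L))
  for (e in seq_len(ne))
    out[e, , ] <- filters$weights %*% epochs$data[e, idx, , drop = TRUE]
  structure(list(data = out, srate = epochs$srate, band = filters$band,
                 roi_names = filters$roi_names),
            class = "virtual_ts")
}

#' @export
print.virtual_ts <- function(x, ...) {
  cat(sprintf("<virtual_ts> %d epochs x %d ROIs x %d samples, band %.1f-%.1f Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$band[1], x$band[2]))
  invisible(x)
}

#' Per-ROI band power of the virtual time series
#'
#' Variance of each ROI's reconstructed activity pooled over epochs and
#' samples.
#'
#' @param vts a `virtual_ts`
#' @return named numeric vector, one value per ROI
#' @export
source_band_power <- function(vts) {
  nroi <- dim(vts$data)[2]
  p <- vapply(seq_len(nroi), function(q) stats::var(as.vector(vts$data[, q, ])),
              numeric(1))
  names(p) <- vts$roi_names
  p
}
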