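# Feature stage 4: functional connectivity between the 100 virtual ROI
# time series — phase coupling via the debiased weighted phase-lag index
# (dwPLI) and amplitude coupling via the orthogonalized amplitude-envelope
# correlation (AEC). Both are insensitive to zero-lag (volume-conducted)
# mixing.

#' Debiased weighted phase-lag index, averaged over a band
#'
#' Fourier coefficients of every epoch are taken on a 0.5 Hz grid (one
#' Hann taper per epoch; epochs are zero-padded to an even number of
#' seconds so the grid is exact). Per grid frequency inside the closed
#' band interval, with epochs as observations and `Im X_i` the imaginary
#' cross-spectrum of epoch i, the debiased squared wPLI is
#' `[(sum Im X_i)^2 - sum (Im X_i)^2] / [(sum |Im X_i|)^2 - sum (Im X_i)^2]`;
#' the per-frequency matrices are then averaged over the band's bins.
#' Slightly negative values of the debiased estimator are retained. A band
#' edge not representable on the 0.5 Hz grid is truncated to the highest
#' grid bin at or below it.
#'
#' @param vts a `virtual_ts` (band-limited)
#' @param band numeric `c(lo, hi)` Hz
#' @return a `connectivity_matrix` (symmetric ROI x ROI, diagonal 0,
#'   measure "dwpli")
#' @export
dwpli_band <- function(vts, band = vts$band) {
  ne <- dim(vts$data)[1]
  if (ne < 2) stop("dwPLI needs at least 2 epochs")
  nroi <- dim(vts$data)[2]
  L <- dim(vts$data)[3]
  srate <- vts$srate
  dur <- L / srate
  T_pad <- 2 * ceiling(dur / 2)            # even seconds -> 0.5 Hz exact
  nfft <- as.integer(round(T_pad * srate))
  bins <- seq(ceiling(band[1] / 0.5) * 0.5, floor(band[2] / 0.5) * 0.5, by = 0.5)
  bins <- bins[bins > 0 & bins < srate / 2]
  if (!length(bins)) stop("band contains no 0.5 Hz grid frequencies")
  bin_idx <- as.integer(round(bins * T_pad)) + 1L
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  # Fourier coefficients: [epoch, roi, bin]
  Fr <- array(0, c(ne, nroi, length(bins)))
  Fi <- array(0, c(ne, nroi, length(bins)))
  for (e in seq_len(ne)) {
    X <- t(vts$data[e, , , drop = TRUE])   # samples x roi
    X <- sweep(X, 2, colMeans(X)) * hann
    Xp <- rbind(X, matrix(0, nfft - L, nroi))
    Fc <- stats::mvfft(Xp)[bin_idx, , drop = FALSE]
    Fr[e, , ] <- t(Re(Fc)); Fi[e, , ] <- t(Im(Fc))
  }
  acc <- matrix(0, nroi, nroi)
  for (k in seq_along(bins)) {
    s <- .dwpli_sums(Fr[, , k, drop = TRUE], Fi[, , k, drop = TRUE])
    num <- s$s1^2 - s$s2
    den <- s$s3^2 - s$s2
    m <- ifelse(abs(den) < 1e-300, 0, num / den)
    diag(m) <- 0
    acc <- acc + m
  }
  connectivity_matrix(acc / length(bins), measure = "dwpli", band = band,
                      roi_names = vts$roi_names)
}

#' Orthogonalized amplitude-envelope correlation, averaged over epochs
#'
#' Per epoch the analytic signal of every ROI is computed (FFT Hilbert
#' after a 10% cosine edge taper). For each pair, signal A is
#' orthogonalized with respect to B, `A_orth_B(t) = Im(A conj(B) / |B|)`,
#' the Pearson correlation between `|A_orth_B|` and `|B|` is taken, the
#' two directions are averaged, and epoch matrices are averaged. Pairs
#' with a degenerate (zero-variance) orthogonalized envelope get 0.
#'
#' @param vts a band-limited `virtual_ts`
#' @return a `connectivity_matrix` (measure "aec")
#' @export
aec_band <- function(vts) {
  ne <- dim(vts$data)[1]
  nroi <- dim(vts$data)[2]
  L <- dim(vts$data)[3]
  tap <- tukey_window(L, 0.1)
  acc <- matrix(0, nroi, nroi)
  for (e in seq_len(ne)) {
    X <- t(vts$data[e, , , drop = TRUE]) * tap
    Z <- analytic_signal(X)
    R1 <- .aec_corr_mat(Re(Z), Im(Z))
    acc <- acc + (R1 + t(R1)) / 2
  }
  connectivity_matrix(acc / ne, measure = "aec", band = vts$band,
                      roi_names = vts$roi_names)
}

tukey_window <- function(n, frac = 0.1) {
  w <- rep(1, n)
  m <- max(1L, floor(frac * n / 2))
  ramp <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1)))
  w[seq_len(m)] <- ramp
  w[(n - m + 1L):n] <- rev(ramp)
  w
}

#' Construct a connectivity matrix object
#' @param m symmetric ROI x ROI matrix (diagonal forced to 0)
#' @param measure "dwpli" or "aec"
#' @param band numeric `c(lo, hi)` Hz
#' @param roi_names ROI labels
#' @return a `connectivity_matrix`
#' @export
connectivity_matrix <- function(m, measure, band, roi_names = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("connectivity matrix must be square")
  if (max(abs(m - t(m))) > 1e-9) stop("connectivity matrix must be symmetric")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (!is.null(roi_names)) dimnames(m) <- list(roi_names, roi_names)
  structure(list(matrix = m, measure = measure, band = band,
                 roi_names = roi_names %||% rownames(m)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  v <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf("<connectivity_matrix> %s, band %.1f-%.1f Hz, %d ROIs; range [%.3f, %.3f]\n",
              x$measure, x$band[1], x$band[2], nrow(x$matrix), min(v), max(v)))
  invisible(x)
}
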