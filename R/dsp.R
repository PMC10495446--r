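# Low-level signal-processing primitives shared across the pipeline.
# All filters are zero-phase linear-phase FIR (Hamming windowed sinc);
# convolution is done in the frequency domain with reflection padding.

#' FIR order for a Hamming windowed-sinc design
#'
#' Classic Hamming approximation: N ~ 3.3 / normalized transition width,
#' forced odd so the kernel has an integer group delay.
#' @noRd
fir_order <- function(trans_hz, srate, max_order = NULL) {
  n <- ceiling(3.3 / (trans_hz / srate))
  if (!is.null(max_order)) n <- min(n, max_order)
  if (n %% 2L == 0L) n <- n + 1L
  max(n, 5L)
}

#' Windowed-sinc low-pass kernel (odd length, unit DC gain)
#' @noRd
fir_lowpass_kernel <- function(n_taps, cutoff_hz, srate) {
  stopifnot(n_taps %% 2L == 1L)
  m <- (n_taps - 1L) / 2L
  t <- seq(-m, m)
  fc <- cutoff_hz / srate          # cycles per sample
  h <- 2 * fc * sinc(2 * fc * t)
  w <- 0.54 + 0.46 * cos(pi * t / m)  # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' High-pass kernel by spectral inversion of a low-pass at the same cutoff
#' @noRd
fir_highpass_kernel <- function(cutoff_hz, trans_hz, srate, max_order = NULL) {
  n <- fir_order(trans_hz, srate, max_order)
  h <- -fir_lowpass_kernel(n, cutoff_hz, srate)
  h[(n + 1L) / 2L] <- h[(n + 1L) / 2L] + 1
  h
}

#' Band-pass kernel: difference of two low-passes
#' @noRd
fir_bandpass_kernel <- function(lo_hz, hi_hz, trans_hz, srate, max_order = NULL) {
  n <- fir_order(trans_hz, srate, max_order)
  hlo <- fir_lowpass_kernel(n, hi_hz, srate)
  hhi <- fir_lowpass_kernel(n, lo_hz, srate)
  hlo - hhi
}

#' Zero-phase FIR filtering of a channels x samples matrix
#'
#' The kernel must be odd-length symmetric (linear phase). Reflection
#' padding of half the kernel length plus a margin limits edge transients;
#' FFT overlap-free convolution, then the group delay is removed exactly.
#' @noRd
fir_filter_matrix <- function(x, h) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  nh <- length(h)
  m <- (nh - 1L) / 2L
  ns <- ncol(x)
  pad <- min(ns - 1L, nh)
  # reflect-pad each row
  idx_pre <- pmin(pad + 1L, ns):2L
  idx_post <- (ns - 1L):max(1L, ns - pad)
  xp <- cbind(x[, idx_pre, drop = FALSE], x, x[, idx_post, drop = FALSE])
  np <- ncol(xp)
  nfft <- 2^ceiling(log2(np + nh - 1L))
  H <- stats::fft(c(h, numeric(nfft - nh)))
  out <- matrix(0, nrow(x), ns)
  for (i in seq_len(nrow(x))) {
    X <- stats::fft(c(xp[i, ], numeric(nfft - np)))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
    # remove group delay m and the leading reflection pad
    out[i, ] <- y[(length(idx_pre) + m + 1L):(length(idx_pre) + m + ns)]
  }
  out
}

#' Analytic signal via FFT (columns of a samples x channels matrix)
#' @noRd
analytic_signal <- function(x) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  z <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  if (single) drop(z) else z
}

#' Slepian (DPSS) tapers
#'
#' Computed from the classic symmetric tridiagonal eigenproblem; returns the
#' first `k` tapers as columns, each with unit energy, ordered by
#' decreasing eigenvalue (concentration).
#'
#' @param n taper length in samples
#' @param nw time-bandwidth product
#' @param k number of tapers
#' @return n x k matrix of tapers
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  w <- nw / n
  t <- 0:(n - 1L)
  dg <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- (1:(n - 1L)) * (n - (1:(n - 1L))) / 2
  tri <- matrix(0, n, n)
  diag(tri) <- dg
  tri[cbind(1:(n - 1L), 2:n)] <- od
  tri[cbind(2:n, 1:(n - 1L))] <- od
  e <- eigen(tri, symmetric = TRUE)
  tp <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tp[, j]
    v <- v / sqrt(sum(v^2))
    # sign convention: positive mean for symmetric tapers, positive initial slope otherwise
    s <- sum(v)
    if (abs(s) < 1e-10) s <- v[which.max(abs(v))]
    if (s < 0) v <- -v
    tp[, j] <- v
  }
  tp
}

#' Simple one-sided periodogram PSD (Hann taper), for diagnostics/heuristics
#' @noRd
periodogram_psd <- function(x, srate, nfft = NULL) {
  n <- length(x)
  if (is.null(nfft)) nfft <- n
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  w <- w / sqrt(sum(w^2))
  X <- stats::fft(c((x - mean(x)) * w, numeric(max(0L, nfft - n))))
  nf <- floor(nfft / 2) + 1L
  p <- (Mod(X[seq_len(nf)])^2) / srate
  p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  list(freq = (seq_len(nf) - 1L) * srate / nfft, power = p)
}

#' Welch PSD over sliding windows, averaged
#' @noRd
welch_psd <- function(x, srate, win_s = 2, overlap = 0.5) {
  n <- length(x)
  nw <- min(n, round(win_s * srate))
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  acc <- NULL
  for (s in starts) {
    pg <- periodogram_psd(x[s:(s + nw - 1L)], srate)
    acc <- if (is.null(acc)) pg$power else acc + pg$power
  }
  list(freq = pg$freq, power = acc / length(starts))
}
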