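# Stage 4a: Independent Component Analysis.
# Batch extended Infomax (the runica family): natural-gradient updates
# with a sub/super-Gaussian switching matrix, random block order per pass,
# and learning-rate annealing. Annealing makes termination well-defined
# even when part of the whitened space is Gaussian (hence rotationally
# unidentifiable), which is the norm for resting EEG background. After
# average referencing the data rank is one below the channel count, so the
# decomposition size defaults to the numerical rank.

#' Fit ICA on the EEG channels of a recording
#'
#' @param rec an `eeg_recording` (high-passed, bad channels removed)
#' @param seed RNG seed (block permutations and kurtosis subsampling);
#'   the decomposition is reproducible given the seed
#' @param n_comp number of components; defaults to the numerical rank of
#'   the channel covariance (channel count minus one after average reference)
#' @param max_steps maximum training passes over the data
#' @param w_change convergence threshold on the per-pass weight change
#' @return an `ic_decomposition`: `unmixing` (ICs x channels), `mixing`
#'   (channels x ICs), `activations` (ICs x samples), `channel_names`, `seed`
#' @export
fit_ica <- function(rec, seed = 1L, n_comp = NULL, max_steps = 512L,
                    w_change = 1e-6) {
  eeg <- chan_idx(rec, "EEG")
  X <- rec$data[eeg, , drop = FALSE]
  ns <- ncol(X)
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / ns
  e <- eigen(C, symmetric = TRUE)
  if (is.null(n_comp)) n_comp <- sum(e$values > max(e$values) * 1e-9)
  n_comp <- min(n_comp, nrow(X))
  d <- e$values[seq_len(n_comp)]
  E <- e$vectors[, seq_len(n_comp), drop = FALSE]
  sphere <- diag(1 / sqrt(d), n_comp) %*% t(E)    # n_comp x nch
  desphere <- E %*% diag(sqrt(d), n_comp)         # nch x n_comp
  Z <- sphere %*% X

  fit <- with_seed(seed, infomax_train(Z, max_steps = max_steps,
                                       w_change = w_change))
  if (!fit$converged)
    stop(sprintf("ICA did not converge: %d steps, weight change %.3g (threshold %.3g)",
                 fit$steps, fit$last_change, w_change))
  unmixing <- fit$W %*% sphere
  mixing <- desphere %*% solve(fit$W)
  # deterministic component order/sign: sort by projected variance, fix sign
  S <- unmixing %*% X
  vr <- apply(S, 1, stats::var) * colSums(mixing^2)
  ord <- order(vr, decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  for (i in seq_len(n_comp)) {
    j <- which.max(abs(mixing[, i]))
    if (mixing[j, i] < 0) { mixing[, i] <- -mixing[, i]; unmixing[i, ] <- -unmixing[i, ] }
  }
  structure(list(unmixing = unmixing, mixing = mixing,
                 activations = unmixing %*% rec$data[eeg, , drop = FALSE],
                 channel_names = rec$channels$name[eeg],
                 n_iter = fit$steps, seed = seed),
            class = "ic_decomposition")
}

# batch extended Infomax on sphered data Z (n x N): natural-gradient block
# updates (compiled inner loop) with learning-rate annealing; returns the
# rotation W
infomax_train <- function(Z, max_steps = 512L, w_change = 1e-6,
                          anneal_deg = 60, anneal_step = 0.98) {
  n <- nrow(Z); N <- ncol(Z)
  block <- as.integer(min(max(ceiling(5 * log(N)), 256L), floor(N / 3)))
  lrate <- 0.00065 / log(n)
  W <- diag(n)
  signs <- rep(1, n)                 # +1 super-Gaussian, -1 sub-Gaussian
  kurt_every <- 10L                  # blocks between kurtosis-sign updates
  n_blocks <- N %/% block
  n_kupd <- max(1L, n_blocks %/% kurt_every)
  ksz <- min(3000L, N)
  old_dW <- NULL
  oldW <- W
  change <- Inf
  step <- 0L
  while (step < max_steps) {
    step <- step + 1L
    perm <- sample.int(N) - 1L
    kurt_idx <- matrix(replicate(n_kupd, sample.int(N, ksz) - 1L),
                       nrow = n_kupd, byrow = TRUE)
    res <- .infomax_pass(W, Z, perm, block, lrate, signs, kurt_idx, kurt_every)
    if (res$blowup) {                # blow-up: cool down and restart
      lrate <- lrate * 0.5
      W <- diag(n); oldW <- W; old_dW <- NULL
      next
    }
    W <- res$W
    signs <- as.vector(res$signs)
    dW <- W - oldW
    change <- sum(dW^2)
    if (!is.null(old_dW)) {
      denom <- sqrt(sum(dW^2) * sum(old_dW^2))
      angle <- if (denom > 0) acos(max(-1, min(1, sum(dW * old_dW) / denom))) * 180 / pi else 0
      if (angle > anneal_deg) lrate <- lrate * anneal_step
    }
    old_dW <- dW
    oldW <- W
    if (change < w_change && step > 2L) break
  }
  list(W = W, steps = step, converged = change < w_change || step <= 2L,
       last_change = change)
}

#' @export
print.ic_decomposition <- function(x, ...) {
  cat(sprintf("<ic_decomposition> %d ICs over %d channels (seed %d, %d training passes)\n",
              nrow(x$unmixing), ncol(x$unmixing), x$seed, x$n_iter))
  invisible(x)
}

#' Heuristic 7-class IC classification
#'
#' Scores every independent component against the seven canonical classes
#' (Brain, Muscle, Eye, Heart, Line Noise, Channel Noise, Other) from
#' simple spectral, topographic and auxiliary-channel features, and
#' normalizes the scores to a probability vector. Heuristics: Eye needs a
#' high correlation with an EOG channel and/or dominant sub-3-Hz power with
#' a frontal topography gradient; Muscle a rising 20-45 Hz log-spectral
#' slope with focal topography; Line Noise a dominant line-frequency bin;
#' Channel Noise a single-channel loading; Heart a ~1 Hz periodic envelope
#' autocorrelation; Brain a 1/f spectrum with a band peak. Any external
#' classifier returning the same ICs x 7 probability matrix can be used in
#' its place downstream.
#'
#' @param decomp an `ic_decomposition`
#' @param rec the recording it was fitted on (EOG/ECG channels are used
#'   when present)
#' @return matrix ICs x 7 of class probabilities (rows sum to 1)
#' @export
classify_ics <- function(decomp, rec) {
  classes <- c("Brain", "Muscle", "Eye", "Heart", "Line Noise", "Channel Noise", "Other")
  nic <- nrow(decomp$unmixing)
  S <- decomp$activations
  srate <- rec$srate
  eog_idx <- chan_idx(rec, "EOG")
  ecg_idx <- chan_idx(rec, "ECG")
  eeg_names <- decomp$channel_names
  pos <- chan_positions(rec)[match(eeg_names, rec$channels$name), , drop = FALSE]
  frontal <- !is.na(pos[, 2]) & pos[, 2] > 0.04      # anterior electrodes
  scores <- matrix(0, nic, length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(nic)) {
    s <- S[i, ]
    ps <- welch_psd(s, srate, win_s = min(2, length(s) / srate))
    f <- ps$freq; p <- ps$power
    tot <- sum(p) + 1e-30
    low <- sum(p[f < 3]) / tot
    alpha_theta_peak <- {
      inb <- f >= 4 & f <= 13
      if (any(inb) && any(f > 13 & f < 30)) {
        mean(p[inb]) / (mean(p[f > 13 & f < 30]) + 1e-30)
      } else 0
    }
    # log-spectral slope 20-45 Hz
    hi_band <- f >= 20 & f <= min(45, srate / 2 - 1)
    slope <- if (sum(hi_band) > 3)
      stats::coef(stats::lm(log10(p[hi_band] + 1e-30) ~ f[hi_band]))[2] else 0
    # broadband log-log slope 2-40 Hz (1/f-ness)
    bb <- f >= 2 & f <= min(40, srate / 2 - 1)
    bslope <- if (sum(bb) > 3)
      stats::coef(stats::lm(log10(p[bb] + 1e-30) ~ log10(f[bb])))[2] else 0
    topo <- abs(decomp$mixing[, i]); topo <- topo / max(sum(topo), 1e-30)
    focal <- max(topo)
    frontal_grad <- if (any(frontal) && any(!frontal))
      mean(topo[frontal]) / (mean(topo[!frontal]) + 1e-30) else 1
    eog_cor <- if (length(eog_idx))
      max(abs(stats::cor(s, t(rec$data[eog_idx, , drop = FALSE])))) else 0
    ecg_cor <- if (length(ecg_idx))
      max(abs(stats::cor(s, t(rec$data[ecg_idx, , drop = FALSE])))) else 0
    # line-frequency dominance
    line_sc <- 0
    if (!is.na(rec$line_freq) && rec$line_freq < srate / 2) {
      nb <- abs(f - rec$line_freq) <= 1
      ref <- f >= rec$line_freq - 12 & f <= rec$line_freq - 4
      if (any(nb) && any(ref)) line_sc <- mean(p[nb]) / (mean(p[ref]) + 1e-30)
    }
    # ~1 Hz periodicity of the envelope (cardiac template)
    env <- abs(s - mean(s))
    lags <- round(seq(0.6, 1.4, by = 0.05) * srate)
    lags <- lags[lags < length(env) / 2]
    heart_ac <- if (length(lags)) max(vapply(lags, function(L)
      suppressWarnings(stats::cor(env[1:(length(env) - L)], env[(L + 1):length(env)])),
      0), na.rm = TRUE) else 0

    sc <- c(Brain = 0, Muscle = 0, Eye = 0, Heart = 0,
            `Line Noise` = 0, `Channel Noise` = 0, Other = 0.15)
    if (eog_cor >= 0.8) sc["Eye"] <- sc["Eye"] + 12 * eog_cor
    if (low > 0.5 && frontal_grad > 1.5) sc["Eye"] <- sc["Eye"] + 2 * low * min(frontal_grad / 2, 2)
    if (slope > 0 && focal > 0.15) sc["Muscle"] <- sc["Muscle"] + 3 * min(slope * 20, 2) * focal * 5
    if (line_sc > 5) sc["Line Noise"] <- sc["Line Noise"] + min(line_sc / 5, 4)
    if (focal > 0.5) sc["Channel Noise"] <- sc["Channel Noise"] + 4 * (focal - 0.5)
    if (ecg_cor >= 0.6) sc["Heart"] <- sc["Heart"] + 6 * ecg_cor
    if (heart_ac > 0.4 && low < 0.5) sc["Heart"] <- sc["Heart"] + heart_ac
    if (bslope < -0.3 && bslope > -3 && alpha_theta_peak > 1 && sc["Eye"] < 1)
      sc["Brain"] <- sc["Brain"] + 1.5 * min(alpha_theta_peak, 3) * min(-bslope, 2)
    if (bslope < 0 && sc["Eye"] < 1 && slope <= 0)
      sc["Brain"] <- sc["Brain"] + 0.8
    scores[i, ] <- sc / sum(sc)
  }
  scores
}

#' Subtract artifactual ICs from the data
#'
#' Components whose probability of any class in `ic_reject_classes`
#' (default Muscle, Eye) exceeds `ic_reject_prob` (default 0.8) are zeroed
#' and the channel data reconstructed from the remaining components.
#'
#' @param rec the recording the decomposition was fitted on
#' @param decomp an `ic_decomposition`
#' @param cls ICs x 7 probability matrix from [classify_ics()]
#' @param params an `eeg_params` list
#' @return list: `rec` (cleaned recording), `removed` (IC indices),
#'   `probabilities` (their class probabilities)
#' @export
reject_ics <- function(rec, decomp, cls, params = default_params()) {
  bad <- which(apply(cls[, params$ic_reject_classes, drop = FALSE], 1, max) >
                 params$ic_reject_prob)
  if (length(bad)) {
    eeg <- match(decomp$channel_names, rec$channels$name)
    X <- rec$data[eeg, , drop = FALSE]
    rm_part <- decomp$mixing[, bad, drop = FALSE] %*%
      (decomp$unmixing[bad, , drop = FALSE] %*% X)
    rec$data[eeg, ] <- X - rm_part
  }
  list(rec = rec, removed = bad,
       probabilities = cls[bad, , drop = FALSE])
}
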