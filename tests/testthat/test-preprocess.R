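# The seven-stage preprocessing chain.

test_that("line-noise regression removes the line without notching neighbours", {
  srate <- 250; n <- srate * 30
  set.seed(11)
  noise <- rnorm(n)
  line <- sqrt(2) * sin(2 * pi * 50 * (seq_len(n) - 1) / srate)   # SNR 0 dB
  rec <- eeg_recording(matrix(noise + line, 1), srate,
                       data.frame(name = "a", type = "EEG"), line_freq = 50)
  out <- remove_line_noise(rec)
  p_in <- resteeg:::welch_psd(noise + line, srate, 4)
  p_out <- resteeg:::welch_psd(out$data[1, ], srate, 4)
  b50 <- p_in$freq >= 49.5 & p_in$freq <= 50.5
  b40 <- p_in$freq >= 40 & p_in$freq <= 45
  expect_lt(10 * log10(sum(p_out$power[b50]) / sum(p_in$power[b50])), -20)
  expect_lt(abs(10 * log10(sum(p_out$power[b40]) / sum(p_in$power[b40]))), 1)

  # no line component: near no-op
  rec0 <- eeg_recording(matrix(noise, 1), srate,
                        data.frame(name = "a", type = "EEG"), line_freq = 50)
  out0 <- remove_line_noise(rec0)
  expect_lt(stats::sd(out0$data[1, ] - noise) / stats::sd(noise), 0.005)

  # drifting amplitude: residual below neighbour-bin level
  drift <- (1 + 0.5 * sin(2 * pi * 0.05 * (seq_len(n) - 1) / srate)) * line
  recd <- eeg_recording(matrix(noise + drift, 1), srate,
                        data.frame(name = "a", type = "EEG"), line_freq = 50)
  outd <- remove_line_noise(recd)
  pd <- resteeg:::welch_psd(outd$data[1, ], srate, 4)
  at50 <- mean(pd$power[abs(pd$freq - 50) <= 0.25])
  nb <- mean(pd$power[pd$freq >= 46 & pd$freq <= 48])
  expect_lt(at50, 2 * nb)

  rec$line_freq <- NA
  expect_error(remove_line_noise(rec), "line_freq")
})

test_that("high-pass filter rejects DC and drifts but preserves the passband", {
  srate <- 250
  tt <- (seq_len(srate * 40) - 1) / srate
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * tt),
                             sin(2 * pi * 0.1 * tt),
                             rep(5, length(tt))), srate,
                       data.frame(name = c("a", "b", "c"), type = "EEG"))
  out <- highpass_filter(rec)
  expect_lt(abs(mean(out$data[3, ])), 1e-3 * 5)
  expect_lt(20 * log10(stats::sd(out$data[2, ]) / stats::sd(rec$data[2, ])), -20)
  expect_lt(abs(stats::sd(out$data[1, ]) / stats::sd(rec$data[1, ]) - 1), 0.01)
})

test_that("flat-run criterion respects the 5-second threshold", {
  sim <- fixture_clean_sim()
  rec <- sim$rec
  i <- match("P4", rec$channels$name)
  rec6 <- rec; rec6$data[i, 2501:(2501 + 6 * 250 - 1)] <- 0   # 6 s > 5 s
  rep6 <- detect_bad_channels(highpass_filter(rec6), raw = rec6)
  expect_true(rep6$report$flat[rep6$report$name == "P4"])
  rec4 <- rec; rec4$data[i, 2501:(2501 + 4 * 250 - 1)] <- 0   # 4 s < 5 s
  rep4 <- detect_bad_channels(highpass_filter(rec4), raw = rec4)
  expect_false(rep4$report$flat[rep4$report$name == "P4"])
})

test_that("detector flags injected artifact channels, keeps clean ones", {
  sim <- fixture_artifact_sim()
  rec <- sim$rec
  rep <- detect_bad_channels(highpass_filter(rec), raw = rec)
  arts <- sim$manifest$artifacts
  flat_ch <- arts$channel[arts$type == "flat"]
  noisy_ch <- arts$channel[arts$type == "noisy"]
  expect_true(all(c(flat_ch, noisy_ch) %in% rep$removed))   # sensitivity 1.0
  expect_lte(length(setdiff(rep$removed, c(flat_ch, noisy_ch))), 1)
})

test_that("too few surviving channels is an error", {
  set.seed(13)
  rec <- eeg_recording(matrix(rnorm(4 * 2500), 4), 250,
                       cbind(standard_montage(4), status = "good"))
  expect_error(detect_bad_channels(rec), "fewer than 8")
})

test_that("average reference zeroes the channel mean and can restore FCz", {
  sim <- fixture_clean_sim()
  rr <- rereference_average(sim$rec)
  eeg <- which(rr$channels$type == "EEG")
  expect_lt(max(abs(colMeans(rr$data[eeg, ]))), 1e-9)
  expect_equal(rr$reference, "average")
  # idempotence
  rr2 <- rereference_average(rr)
  expect_equal(rr2$data, rr$data)
  # add back the original reference channel
  rb <- rereference_average(sim$rec, add_back_ref = TRUE)
  expect_equal(n_channels(rb), n_channels(sim$rec) + 1)
  expect_true("FCz" %in% rb$channels$name)
})

test_that("ICA recovers super-Gaussian sources and is seed-deterministic", {
  set.seed(5)
  n <- 5000
  S <- matrix(0, 3, n)
  for (i in 1:3) { x <- rnorm(n); S[i, ] <- sign(x) * x^2 }
  A <- matrix(rnorm(18), 6, 3)
  rec <- eeg_recording(A %*% S, 250,
                       data.frame(name = letters[1:6], type = "EEG"))
  dec <- fit_ica(rec, seed = 11, n_comp = 3)
  cc <- abs(stats::cor(t(dec$activations), t(S)))
  expect_true(all(apply(cc, 2, max) >= 0.95))
  dec2 <- fit_ica(rec, seed = 11, n_comp = 3)
  expect_identical(dec$unmixing, dec2$unmixing)
  expect_lt(max(abs(dec$unmixing %*% dec$mixing - diag(3))), 1e-6)
})

test_that("ICA size defaults to the rank after average referencing", {
  sim <- fixture_clean_sim()
  rr <- rereference_average(highpass_filter(sim$rec))
  dec <- fit_ica(rr, seed = 2)
  expect_equal(nrow(dec$unmixing), sum(rr$channels$type == "EEG") - 1)
})

test_that("IC classifier identifies blinks and brain rhythms", {
  cfg <- sim_config(duration_s = 60, seed = 7, artifacts = list(
    blinks = list(times_s = seq(3, 55, by = 5), amp = 150)))
  sim <- simulate_recording(cfg, leadfield = fixture_leadfield(),
                            atlas = fixture_atlas())
  rr <- rereference_average(highpass_filter(remove_line_noise(sim$rec)))
  dec <- fit_ica(rr, seed = 1001)
  cls <- classify_ics(dec, rr)
  expect_lt(max(abs(rowSums(cls) - 1)), 1e-9)
  expect_true(all(cls >= 0))
  # the blink component (max |corr| with VEOG) must be called Eye
  eog <- which(rr$channels$type == "EOG")
  cors <- abs(stats::cor(t(dec$activations), rr$data[eog, ]))
  expect_gt(cls[which.max(cors), "Eye"], 0.8)
  # an IC dominated by a 10 Hz rhythm on a 1/f background is Brain
  alpha_ic <- which.max(vapply(seq_len(nrow(cls)), function(i) {
    ps <- resteeg:::welch_psd(dec$activations[i, ], rr$srate, 2)
    mean(ps$power[ps$freq >= 8 & ps$freq <= 13]) /
      mean(ps$power[ps$freq >= 15 & ps$freq <= 30])
  }, numeric(1)))
  expect_equal(colnames(cls)[which.max(cls[alpha_ic, ])], "Brain")
})

test_that("IC rejection applies the 80% probability rule", {
  sim <- fixture_clean_sim()
  rr <- rereference_average(highpass_filter(sim$rec))
  dec <- fit_ica(rr, seed = 3)
  nic <- nrow(dec$unmixing)
  cls <- matrix(0, nic, 7,
                dimnames = list(NULL, c("Brain", "Muscle", "Eye", "Heart",
                                        "Line Noise", "Channel Noise", "Other")))
  cls[, "Brain"] <- 1
  cls[2, ] <- 0; cls[2, "Eye"] <- 0.9; cls[2, "Brain"] <- 0.1
  rj <- reject_ics(rr, dec, cls)
  expect_equal(rj$removed, 2L)
  # all ICs at 0.5: exact no-op
  cls05 <- matrix(1 / 7, nic, 7, dimnames = dimnames(cls))
  cls05[, "Eye"] <- 0.5; cls05 <- cls05 / rowSums(cls05)
  rj0 <- reject_ics(rr, dec, cls05)
  expect_identical(rj0$rec$data, rr$data)
  expect_length(rj0$removed, 0)
})

test_that("spherical-spline interpolation reconstructs a held-out channel", {
  sim <- fixture_clean_sim()
  hp <- highpass_filter(sim$rec)
  victim <- "Cz"
  report <- structure(list(report = NULL, removed = victim),
                      class = "bad_channel_report")
  reduced <- remove_channels(hp, victim)
  rec2 <- interpolate_channels(reduced, report, hp$channels)
  expect_identical(rec2$channels$name, hp$channels$name)   # order restored
  expect_equal(n_channels(rec2), n_channels(hp))
  i <- match(victim, hp$channels$name)
  expect_gt(stats::cor(rec2$data[i, ], hp$data[i, ]), 0.95)
  # empty report: identity
  rec3 <- interpolate_channels(hp, structure(list(removed = character()),
                                             class = "bad_channel_report"),
                               hp$channels)
  expect_identical(rec3$data, hp$data)
})

test_that("ASR calibration keeps clean windows and rejects bursting ones", {
  sim <- fixture_clean_sim()
  rr <- rereference_average(highpass_filter(sim$rec))
  calib <- asr_calibrate(rr)
  expect_equal(length(calib$kept_windows), calib$n_windows)  # fully clean
  expect_true(all(calib$variance > 0))
  # 3/26 channels bursting in one window (11.5% > 7.5%) -> window excluded
  rec_b <- rr
  burst_ch <- match(c("Fp1", "Fp2", "F7"), rec_b$channels$name)
  rec_b$data[burst_ch, 5001:5250] <- rec_b$data[burst_ch, 5001:5250] +
    matrix(rnorm(3 * 250, sd = 300), 3)
  calib_b <- asr_calibrate(rec_b)
  burst_windows <- which(vapply(seq_len(calib_b$n_windows), function(w) {
    s <- (w - 1) * 125   # 1-s windows, 50% overlap at 250 Hz
    s < 5250 && s + 250 > 5000
  }, logical(1)))
  expect_false(any(burst_windows %in% calib_b$kept_windows))
  # too-short recording errors
  short <- rr; short$data <- short$data[, 1:500]
  expect_error(asr_calibrate(short), "5 s")
})

test_that("ASR flags burst samples and spares clean data", {
  sim <- fixture_artifact_sim()
  rec <- sim$rec
  rep <- detect_bad_channels(highpass_filter(rec), raw = rec)
  rr <- rereference_average(apply_bad_channels(highpass_filter(rec), rep))
  calib <- asr_calibrate(rr)
  mask <- asr_flag_segments(rr, calib)
  expect_length(mask$mask, n_samples(rr))
  b <- sim$manifest$artifacts[sim$manifest$artifacts$type == "burst", ]
  burst_idx <- (b$start + 1):b$end
  expect_gte(mean(mask$mask[burst_idx]), 0.9)
  margin <- 250
  clean_idx <- setdiff(seq_len(n_samples(rr)),
                       (b$start - margin):(b$end + margin))
  expect_lte(mean(mask$mask[clean_idx]), 0.05)
  # clean fixture: under 2% flagged
  sim0 <- fixture_clean_sim()
  rr0 <- rereference_average(highpass_filter(sim0$rec))
  m0 <- asr_flag_segments(rr0, asr_calibrate(rr0))
  expect_lt(mean(m0$mask), 0.02)
})

test_that("mask stabilization selects the repetition closest to the mean", {
  cfg <- sim_config(duration_s = 40, seed = 31, artifacts = list(
    bursts = list(list(start_s = 25, end_s = 26, amp = 500))))
  sim <- simulate_recording(cfg, leadfield = fixture_leadfield(),
                            atlas = fixture_atlas())
  rr <- rereference_average(highpass_filter(remove_line_noise(sim$rec)))
  p3 <- merge_params(list(n_ica_repetitions = 3))
  st <- stabilize_and_clean(rr, p3)
  expect_equal(st$diagnostics$selected,
               which.min(st$diagnostics$l1_to_mean))
  expect_true(all(st$diagnostics$l1_to_mean >=
                    st$diagnostics$l1_to_mean[st$diagnostics$selected]))
  # single repetition degenerates to one pass
  p1 <- merge_params(list(n_ica_repetitions = 1))
  st1 <- stabilize_and_clean(rr, p1)
  expect_equal(st1$diagnostics$selected, 1L)
  # rejected fraction of the selected repetition is within +-50% of the
  # single-pass fraction (same base seed)
  f_multi <- st$diagnostics$rejected_fraction[st$diagnostics$selected]
  f_single <- st1$diagnostics$rejected_fraction[1]
  expect_lt(abs(f_multi - f_single), max(0.5 * f_single, 0.02))
})

test_that("epoching follows the overlap grid and boundary rejection rule", {
  set.seed(17)
  rec <- eeg_recording(matrix(rnorm(2 * 2500), 2), 250,
                       data.frame(name = c("a", "b"), type = "EEG"))
  p <- default_params()
  expect_equal(n_epochs(epoch_data(rec, p)), 9)        # 10 s, 2 s, 50%
  # boundary at 5.0 s: enumerate starts 0..8 s, drop those with
  # start < 5 < start+2 strictly -> only the 4-s epoch is cut
  recb <- rec; recb$boundaries <- 1250L
  starts <- 0:8
  expected <- sum(!(starts < 5 & 5 < starts + 2))
  expect_equal(n_epochs(epoch_data(recb, p)), expected)
  # zero overlap: disjoint epochs
  p0 <- p; p0$epoch_overlap <- 0.5
  p0$epoch_overlap <- 1e-9   # validator forbids exactly 0; step == length
  ep0 <- epoch_data(rec, p0)
  expect_equal(n_epochs(ep0), floor(10 / 2))
  expect_true(all(diff(ep0$starts) == 500))
  # too-short recording
  short <- rec; short$data <- short$data[, 1:100, drop = FALSE]
  expect_error(epoch_data(short, p), "epoch")
})

test_that("channel count is restored and the chain is deterministic", {
  sim <- fixture_artifact_sim(seed = 5)
  p <- merge_params(list(n_ica_repetitions = 2))
  pp <- preprocess_recording(sim$rec, p)
  eeg_ct <- sum(pp$epochs$channels$type == "EEG")
  expect_equal(eeg_ct, sum(sim$rec$channels$type == "EEG"))
  pp2 <- preprocess_recording(sim$rec, p)
  expect_equal(pp$epochs$data, pp2$epochs$data, tolerance = 1e-12)
  expect_identical(pp$runlog$rejected_channels, pp2$runlog$rejected_channels)
})

test_that("preprocessing an already-clean recording preserves band power", {
  sim <- fixture_clean_sim(seed = 19)
  p <- merge_params(list(n_ica_repetitions = 2))
  pp <- preprocess_recording(sim$rec, p)
  band_pow <- function(rec) {
    pw <- 0
    eeg <- which(rec$channels$type == "EEG")
    for (i in eeg) {
      ps <- resteeg:::welch_psd(rec$data[i, ], rec$srate, 2)
      sel <- ps$freq >= 1 & ps$freq <= 45
      pw <- pw + sum(ps$power[sel]) * (ps$freq[2] - ps$freq[1])
    }
    pw / length(eeg)
  }
  before <- band_pow(highpass_filter(sim$rec))
  after <- band_pow(pp$rec)
  expect_lt(abs(after - before) / before, 0.10)
})
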