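# Domain types, raw-data readers, BIDS sidecars, parameter handling,
# feature writers.

test_that("recording constructor enforces its invariants", {
  ch <- data.frame(name = c("a", "b"), type = "EEG")
  expect_s3_class(eeg_recording(matrix(0, 2, 10), 100, ch), "eeg_recording")
  expect_error(eeg_recording(matrix(0, 3, 10), 100, ch), "channel count")
  expect_error(eeg_recording(matrix(0, 2, 10), -1, ch), "srate")
  expect_error(eeg_recording(matrix(0, 2, 10), 100,
                             data.frame(name = c("a", "a"), type = "EEG")),
               "unique")
  expect_error(eeg_recording(matrix(0, 2, 10), 100, ch, boundaries = 11L),
               "boundary")
  ch$x <- c(0, Inf); ch$y <- 0; ch$z <- 0
  expect_error(eeg_recording(matrix(0, 2, 10), 100, ch), "finite")
})

test_that("BrainVision triplet round-trips data, events and boundaries", {
  # quiet fixture: float32 storage resolves ~1e-7 of full scale, so at
  # ~2 uV amplitudes the absolute round-trip error stays below 1e-6 uV
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(4 * 1000, sd = 0.5), 4), 250,
                       data.frame(name = c("Fz", "Cz", "Pz", "Oz"), type = "EEG"),
                       events = data.frame(sample = c(10L, 500L),
                                           label = c("S  1", "S  2")),
                       boundaries = c(250L, 700L))
  td <- withr::local_tempdir()
  write_brainvision(rec, file.path(td, "rt"))
  rec2 <- read_brainvision(file.path(td, "rt.vhdr"))
  expect_lt(max(abs(rec2$data - rec$data)), 1e-6)
  expect_identical(rec2$boundaries, rec$boundaries)
  expect_identical(rec2$events$sample, rec$events$sample)
  expect_identical(rec2$channels$name, rec$channels$name)
  expect_equal(rec2$srate, rec$srate)
})

test_that("EDF reader recovers a written recording to quantization accuracy", {
  set.seed(2)
  rec <- eeg_recording(matrix(rnorm(3 * 500, sd = 20), 3), 250,
                       data.frame(name = c("C3", "C4", "Cz"), type = "EEG"))
  td <- withr::local_tempdir()
  write_edf(rec, file.path(td, "rt.edf"))
  rec2 <- read_edf(file.path(td, "rt.edf"))
  # 16-bit quantization over +-~80 uV: resolution ~2.5e-3 uV
  expect_lt(max(abs(rec2$data - rec$data[, seq_len(ncol(rec2$data))])), 0.01)
  expect_equal(rec2$srate, 250)
  expect_identical(rec2$channels$name, rec$channels$name)
})

test_that("BIDS reader populates sidecar metadata and validates files", {
  sim <- fixture_clean_sim()
  td <- withr::local_tempdir()
  write_bids_recording(sim$rec, td, "01", task = "rest")
  rec <- read_raw_bids(td, "01")
  expect_equal(rec$line_freq, 50)
  expect_equal(rec$reference, "FCz")
  expect_lt(max(abs(rec$data - sim$rec$data)), 1e-4)
  # missing sidecar is a hard error naming the file
  eegdir <- file.path(td, "sub-01", "eeg")
  json <- list.files(eegdir, pattern = "_eeg\\.json$", full.names = TRUE)
  file.rename(json, paste0(json, ".bak"))
  expect_error(read_raw_bids(td, "01"), "_eeg.json")
  file.rename(paste0(json, ".bak"), json)
  # channel count mismatch is a hard error
  ctsv <- list.files(eegdir, pattern = "_channels\\.tsv$", full.names = TRUE)
  tab <- utils::read.delim(ctsv)
  utils::write.table(tab[-1, ], ctsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_raw_bids(td, "01"), "mismatch")
})

test_that("EEG channels without positions in electrodes.tsv are dropped", {
  sim <- fixture_clean_sim()
  rec <- sim$rec
  # two extra non-standard channels with no electrode entry
  rec$data <- rbind(rec$data, matrix(0, 2, ncol(rec$data)))
  extra <- data.frame(name = c("X1", "X2"), type = "EEG",
                      x = NA_real_, y = NA_real_, z = NA_real_, status = "good")
  rec$channels <- rbind(rec$channels, extra)
  td <- withr::local_tempdir()
  write_bids_recording(rec, td, "02", task = "rest")
  got <- read_raw_bids(td, "02")
  expect_equal(n_channels(got), n_channels(rec) - 2)
  expect_false(any(c("X1", "X2") %in% got$channels$name))
})

test_that("resampling decimates, preserves tones and suppresses aliases", {
  n_in <- 2500 * 4
  tt <- (seq_len(n_in) - 1) / 2500
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * tt), 1), 2500,
                       data.frame(name = "a", type = "EEG"))
  out <- resample_recording(rec, 250)
  expect_equal(ncol(out$data), floor(n_in * 250 / 2500))
  expect_error(resample_recording(out, 300), "below the native rate")
  pg <- resteeg:::periodogram_psd(out$data[1, ], 250)
  expect_lt(abs(pg$freq[which.max(pg$power)] - 10), 0.3)
  # 200 Hz tone is above the new passband edge: >= 40 dB down
  rec2 <- eeg_recording(matrix(sin(2 * pi * 200 * tt), 1), 2500,
                        data.frame(name = "a", type = "EEG"))
  out2 <- resample_recording(rec2, 250)
  # interior samples only: reflection-padding transients live at the edges
  core <- out2$data[1, 200:(ncol(out2$data) - 200)]
  atten_db <- 20 * log10(stats::sd(core) / stats::sd(rec2$data))
  expect_lt(atten_db, -40)
  # total duration preserved within one sample period
  expect_lt(abs(duration_s(out) - duration_s(rec)), 1 / 250)
})

test_that("parameter loading applies defaults, overrides and validation", {
  td <- withr::local_tempdir()
  pj <- file.path(td, "p.json")
  writeLines("{}", pj)
  expect_equal(load_params(pj), default_params())
  writeLines('{"epoch_len_s": 4}', pj)
  p <- load_params(pj)
  expect_equal(p$epoch_len_s, 4)
  expect_equal(p$graph_density, default_params()$graph_density)
  writeLines('{"graph_density": 1.5}', pj)
  expect_error(load_params(pj), "graph_density")
  writeLines('{"nonsense_field": 1}', pj)
  expect_error(load_params(pj), "nonsense_field")
})

test_that("defaults equal the published pipeline values", {
  p <- default_params()
  expected <- list(flat_max_s = 5, noise_z_thresh = 4, predictability_frac = 0.8,
                   ic_reject_prob = 0.8, n_ica_repetitions = 10,
                   asr_calib_noisy_frac = 0.075, asr_rms_z = 5.5, asr_cutoff = 20,
                   epoch_len_s = 2, epoch_overlap = 0.5, lcmv_reg = 0.05,
                   graph_density = 0.2)
  for (nm in names(expected)) expect_equal(p[[nm]], expected[[nm]], info = nm)
  expect_equal(p$bands$theta, c(4, 7.9))
  expect_equal(p$bands$alpha, c(8, 12.9))
  expect_equal(p$bands$beta, c(13, 30))
  expect_equal(p$bands$gamma, c(30.1, 80))
  expect_equal(p$hp_transition_band, c(0.25, 0.75))
})

test_that("feature bundles produce one file per feature and round-trip", {
  # synthetic minimal bundle: 4 bands x 2 measures
  set.seed(5)
  ps <- structure(list(freq = seq(1, 100, by = 0.5),
                       power = matrix(abs(rnorm(3 * 199)), 3),
                       global = abs(rnorm(199)), n_epochs = 10, n_tapers = 3,
                       channel_names = c("a", "b", "c")),
                  class = "power_spectrum")
  conn <- list(); graphs <- list()
  for (b in c("theta", "alpha", "beta", "gamma")) for (m in c("dwpli", "aec")) {
    M <- matrix(rnorm(100), 10); M <- (M + t(M)) / 2; diag(M) <- 0
    cm <- connectivity_matrix(M, m, c(1, 2), paste0("R", 1:10))
    key <- paste(m, b, sep = "_")
    conn[[key]] <- cm
    graphs[[key]] <- graph_metrics(cm, density = 0.2, n_null = 2, seed = 1)
  }
  bundle <- feature_bundle("77", ps, list(peak_maximum_hz = 10.2, cog_hz = 10.4),
                           list(), conn, graphs, default_params())
  td <- withr::local_tempdir()
  paths <- write_feature_bundle(bundle, td)
  expect_equal(sum(grepl("^sub-77_(dwpli|aec)_(theta|alpha|beta|gamma)\\.h5$",
                         basename(paths))), 8)
  expect_equal(sum(grepl("_graph_", paths)), 8)
  expect_true(any(grepl("_params\\.json$", paths)))  # reproducibility dump
  back <- read_feature_bundle(td, "77")
  expect_lt(max(abs(back$connectivity$dwpli_alpha -
                      conn$dwpli_alpha$matrix)), 1e-9)
  expect_equal(back$apf$peak_maximum_hz, 10.2)
  expect_equal(back$params$graph_density, 0.2)
})
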