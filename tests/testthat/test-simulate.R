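# The synthetic-EEG generator and its ground-truth manifests.

test_that("simulation is bit-identical given the seed", {
  cfg <- sim_config(duration_s = 10, seed = 42)
  a <- simulate_recording(cfg, leadfield = fixture_leadfield(),
                          atlas = fixture_atlas())
  b <- simulate_recording(cfg, leadfield = fixture_leadfield(),
                          atlas = fixture_atlas())
  expect_identical(a$rec$data, b$rec$data)
  expect_identical(a$manifest$artifacts, b$manifest$artifacts)
})

test_that("doubling source amplitude quadruples its sensor band power", {
  mk <- function(amp) {
    cfg <- sim_config(duration_s = 40, seed = 5, background = 0.5,
                      sensor_noise = 0.1,
                      sources = list(list(freq = 10, bw = 2, amp = amp, roi = 5)))
    simulate_recording(cfg, leadfield = fixture_leadfield(),
                       atlas = fixture_atlas())
  }
  bandpow <- function(sim) {
    ps <- resteeg:::welch_psd(sim$rec$data[which.max(abs(sim$manifest$mixing[, 1])), ],
                              250, 2)
    sum(ps$power[ps$freq >= 8 & ps$freq <= 12])
  }
  r <- bandpow(mk(8)) / bandpow(mk(4))
  expect_gt(r, 3.4); expect_lt(r, 4.6)
})

test_that("generated spectra show a 1/f background with the alpha peak", {
  sim <- fixture_clean_sim()
  i <- match("O1", sim$rec$channels$name)
  ps <- resteeg:::welch_psd(sim$rec$data[i, ], 250, 2)
  sel <- ps$freq %in% c(2:7, 20:45)
  slope <- stats::coef(stats::lm(log10(ps$power[sel]) ~ log10(ps$freq[sel])))[2]
  expect_gt(slope, -2); expect_lt(slope, -0.5)
  peak_f <- ps$freq[ps$freq >= 5 & ps$freq <= 15][
    which.max(ps$power[ps$freq >= 5 & ps$freq <= 15])]
  expect_lt(abs(peak_f - 10), 1.5)
})

test_that("phase-lag coupling elevates sensor-level coherence", {
  base <- list(sources = list(list(freq = 10, bw = 2, amp = 8, roi = 5),
                              list(freq = 10, bw = 2, amp = 8, roi = 54)),
               duration_s = 40, seed = 6, background = 2, sensor_noise = 0.5)
  cfg_c <- do.call(sim_config, c(base, list(
    couplings = list(list(pair = c(1, 2), type = "phase_lag",
                          strength = 1, lag = pi / 2)))))
  cfg_u <- do.call(sim_config, base)
  coh10 <- function(sim) {
    e1 <- which.max(abs(sim$manifest$mixing[, 1]))
    e2 <- which.max(abs(sim$manifest$mixing[, 2]))
    x <- sim$rec$data[e1, ]; y <- sim$rec$data[e2, ]
    n <- 500; nseg <- floor(length(x) / n)
    Sxy <- Sxx <- Syy <- 0
    for (s in seq_len(nseg)) {
      idx <- ((s - 1) * n + 1):(s * n)
      X <- stats::fft(x[idx])[21]; Y <- stats::fft(y[idx])[21]   # 10 Hz bin
      Sxy <- Sxy + X * Conj(Y); Sxx <- Sxx + Mod(X)^2; Syy <- Syy + Mod(Y)^2
    }
    Mod(Sxy)^2 / (Sxx * Syy)
  }
  sim_c <- simulate_recording(cfg_c, leadfield = fixture_leadfield(),
                              atlas = fixture_atlas())
  sim_u <- simulate_recording(cfg_u, leadfield = fixture_leadfield(),
                              atlas = fixture_atlas())
  expect_gt(coh10(sim_c), coh10(sim_u) + 0.3)
})

test_that("artifact injection matches the manifest exactly", {
  sim <- fixture_artifact_sim()
  arts <- sim$manifest$artifacts
  flat <- arts[arts$type == "flat", ]
  expect_equal(flat$start, 20 * 250)
  expect_equal(flat$end, 26 * 250)
  i <- match(flat$channel, sim$rec$channels$name)
  expect_true(all(sim$rec$data[i, (flat$start + 1):flat$end] == 0))
  burst <- arts[arts$type == "burst", ]
  rms_burst <- sqrt(mean(sim$rec$data[, (burst$start + 1):burst$end]^2))
  clean_cols <- setdiff(seq_len(n_samples(sim$rec)),
                        (burst$start - 250):(burst$end + 250))
  rms_clean <- sqrt(mean(sim$rec$data[, clean_cols]^2))
  expect_gte(rms_burst, 10 * rms_clean)
  # invalid spans are rejected with a message listing the problem
  expect_error(sim_config(duration_s = 10, artifacts = list(
    bursts = list(list(start_s = 8, end_s = 12, amp = 100)))), "span")
  expect_error(sim_config(sources = list(list(freq = 10, bw = 2, amp = 1, roi = 1)),
                          couplings = list(list(pair = c(1, 2), type = "phase_lag",
                                                strength = 1))),
               "undefined source")
})

test_that("blink transients are mirrored on the VEOG channel", {
  cfg <- sim_config(duration_s = 30, seed = 8, artifacts = list(
    blinks = list(times_s = c(5, 12, 20), amp = 200)))
  sim <- simulate_recording(cfg, leadfield = fixture_leadfield(),
                            atlas = fixture_atlas())
  expect_true("VEOG" %in% sim$rec$channels$name)
  expect_equal(sim$rec$channels$type[sim$rec$channels$name == "VEOG"], "EOG")
  # reconstruct the injected train from the manifest and correlate
  blinks <- sim$manifest$artifacts[sim$manifest$artifacts$type == "blink", ]
  train <- numeric(n_samples(sim$rec))
  for (r in seq_len(nrow(blinks))) {
    idx <- (blinks$start[r] + 1):blinks$end[r]
    train[idx] <- sin(pi * seq_along(idx) / length(idx))^2
  }
  veog <- sim$rec$data[sim$rec$channels$name == "VEOG", ]
  expect_gte(stats::cor(veog, train), 0.9)
})

test_that("paired EC/EO datasets express the alpha-attenuation effect", {
  td <- withr::local_tempdir()
  man <- make_paired_dataset(td, n_subjects = 4, alpha_ratio = 0.5, seed = 9)
  expect_equal(nrow(man), 8)
  p <- default_params()
  subs <- bids_subjects(td)
  expect_length(subs, 4)
  ga <- function(task) {
    specs <- vapply(subs, function(s) {
      ps <- multitaper_psd(epoch_data(read_raw_bids(td, s, task = task), p), p)
      sel <- ps$freq >= 8 & ps$freq <= 12.9
      sum(ps$global[sel])
    }, numeric(1))
    mean(specs)
  }
  ratio <- ga("EC") / ga("EO")
  # amplitude halving -> power ratio ~4, diluted by the 1/f background
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.3)
  # and no effect when alpha_ratio is 1
  td2 <- withr::local_tempdir()
  make_paired_dataset(td2, n_subjects = 2, alpha_ratio = 1, seed = 10)
  subs2 <- bids_subjects(td2)
  r2 <- mean(vapply(subs2, function(s) {
    pe <- multitaper_psd(epoch_data(read_raw_bids(td2, s, task = "EC"), p), p)
    po <- multitaper_psd(epoch_data(read_raw_bids(td2, s, task = "EO"), p), p)
    sel <- pe$freq >= 8 & pe$freq <= 12.9
    sum(pe$global[sel]) / sum(po$global[sel])
  }, numeric(1)))
  expect_gt(r2, 0.7); expect_lt(r2, 1.4)
})
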