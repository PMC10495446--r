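# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fixture_atlas <- function() cached("atlas", load_atlas())

fixture_leadfield <- function(n_channels = 26) {
  cached(paste0("lf", n_channels),
         build_spherical_leadfield(fixture_atlas(), standard_montage(n_channels)))
}

# clean 60-s default-condition recording
fixture_clean_sim <- function(seed = 3) {
  cached(paste0("clean", seed), {
    simulate_recording(sim_config(duration_s = 60, seed = seed),
                       leadfield = fixture_leadfield(), atlas = fixture_atlas())
  })
}

# recording with flat channel, noisy channel and a burst
fixture_artifact_sim <- function(seed = 4) {
  cached(paste0("art", seed), {
    cfg <- sim_config(duration_s = 60, seed = seed, artifacts = list(
      flat = list(list(channel = "T8", start_s = 20, end_s = 26)),
      noisy = c("F3"),
      bursts = list(list(start_s = 40, end_s = 41, amp = 500))))
    simulate_recording(cfg, leadfield = fixture_leadfield(), atlas = fixture_atlas())
  })
}

# single-channel sinusoid recording
sine_recording <- function(freq, duration_s = 20, srate = 250, amp = 1) {
  tt <- (seq_len(duration_s * srate) - 1) / srate
  eeg_recording(matrix(amp * sin(2 * pi * freq * tt), 1), srate,
                data.frame(name = "ch1", type = "EEG"))
}

# build a virtual_ts object directly from an epochs x roi x samples array
make_vts <- function(arr, srate = 250, band = c(8, 12.9)) {
  structure(list(data = arr, srate = srate, band = band,
                 roi_names = paste0("R", seq_len(dim(arr)[2]))),
            class = "virtual_ts")
}

make_graph <- function(A) {
  structure(list(adjacency = A, density = sum(A) / (nrow(A) * (nrow(A) - 1)),
                 threshold = NA), class = "binary_graph")
}

# independent brute-force graph oracles (no package code)
oracle_triangles <- function(A) {
  n <- nrow(A)
  t_i <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (j != i && k != i && k != j && A[i, j] && A[i, k] && A[j, k])
      t_i[i] <- t_i[i] + 1
  t_i / 2                      # each unordered pair counted twice
}

oracle_bfs_dist <- function(A, from) {
  n <- nrow(A)
  d <- rep(Inf, n); d[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      nb <- which(A[v, ] == 1)
      new <- nb[d[nb] > d[v] + 1]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

oracle_efficiency <- function(A) {
  n <- nrow(A)
  acc <- 0; np <- 0
  for (i in seq_len(n - 1)) {
    d <- oracle_bfs_dist(A, i)
    for (j in (i + 1):n) {
      acc <- acc + if (is.finite(d[j])) 1 / d[j] else 0
      np <- np + 1
    }
  }
  acc / np
}
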