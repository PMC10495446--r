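---
title: "resteeg: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{resteeg: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`resteeg` is a fully automated pipeline for resting-state EEG: seven
preprocessing stages followed by five feature-extraction stages, with a
synthetic-EEG generator that makes every stage testable against known
ground truth. This vignette explains the methods, the parameters that
matter, the numerical choices, and what the synthetic data can and cannot
tell you about behavior on real recordings.

## The preprocessing chain

Input is a BIDS-organized BrainVision or EDF recording; the power-line
frequency and the reference electrode name are read from the
`*_eeg.json` sidecar and electrode positions (head RAS, meters) from
`*_electrodes.tsv`, falling back to the built-in standard 10-20/10-10
montage for standard channel names. The stages are:

1. **Line-noise removal** — sliding-window (4 s, 50% overlap) sinusoidal
   regression at the line frequency and all harmonics below Nyquist. A
   harmonic is subtracted only where its regression F statistic is
   significant (p < 1e-3), so the spectrum keeps no notch and pure
   broadband signal passes through essentially unchanged. Windowed
   estimates are Hann-crossfaded, which tracks slow drifts in line
   amplitude.
2. **High-pass filtering** — zero-phase Hamming windowed-sinc FIR, -6 dB
   at 0.5 Hz, transition band 0.25–0.75 Hz. All filters in the package
   are this family; zero phase is obtained exactly from the symmetric
   kernel with group-delay compensation and reflection padding.
3. **Bad-channel rejection**, three criteria:
   * *flat*: absolute successive difference below 1e-8 µV over a
     contiguous run longer than 5 s. This is evaluated on the signal
     *before* high-pass filtering: a zero-phase FIR smears neighbouring
     low-frequency energy across a flat span, so no span of practical
     length remains numerically flat afterwards — flatlining is a
     property of the raw amplifier output.
   * *noisy*: noise-to-signal ratio, defined as sd(content above 40 Hz) /
     sd(content below 40 Hz), robust z-scored across channels
     (median / 1.4826·MAD), flagged above z = 4. The estimator split at
     40 Hz separates EMG-band noise from neural signal.
   * *unpredictable*: in 5-s windows, the channel is predicted by
     spherical-spline interpolation from each of 50 random subsets of the
     other channels; a window counts as predicted if the best subset
     reaches correlation ≥ 0.8, and the channel is flagged if fewer than
     80% of windows are predicted. The subset size is 25% of the other
     channels but floored at 10: the spline scalp field is dominated by
     spherical harmonics up to degree ~3 (9–16 basis functions), so
     predictions from fewer electrodes are spatially under-determined on
     sparse (~20-channel) montages and flag clean central channels.
     Already-flagged channels are excluded from the predictor pool.
4. **Average re-referencing** — instantaneous mean over EEG channels
   subtracted; optionally the original reference electrode's time course
   (the negated pre-reference mean) is appended as a new channel.
5. **ICA with automatic component rejection** — batch extended Infomax
   (natural-gradient updates with a sub/super-Gaussian switching matrix,
   random block order, learning-rate annealing) on the rank-reduced
   whitened data; after average referencing the rank is the channel count
   minus one. Annealing matters: most of the whitened background of
   resting EEG is close to Gaussian, so the rotation in that subspace is
   not identifiable and fixed-point algorithms oscillate indefinitely,
   while an annealed learning schedule terminates deterministically.
   Components are scored by a documented heuristic over seven classes
   (Brain, Muscle, Eye, Heart, Line Noise, Channel Noise, Other) using
   EOG/ECG correlations, spectral slopes, line-bin dominance, topography
   focality and envelope periodicity; the scorer returns a probability
   vector per component and any external classifier with the same
   ICs × 7 interface can replace it. Components with P(Muscle) or P(Eye)
   above 0.8 are subtracted.
6. **Spherical-spline interpolation** (order m = 4, 15 Legendre terms,
   ridge 1e-8) restores the rejected channels so the channel count is
   constant across recordings.
7. **Artifact-subspace bad-segment removal** — calibration keeps 1-s
   windows in which fewer than 7.5% of channels have a robust RMS
   z-score above 5.5; the model is the principal axes and variances of
   the retained data. Detection projects sliding 0.5-s windows onto the
   calibration axes and flags a window when the variance along any axis
   exceeds 20× its calibration value; flagged samples are excised and a
   boundary is recorded at each cut. Removal, not subspace
   reconstruction, is implemented.

Because ICA is stochastic, stages 5–7 are repeated `n_ica_repetitions`
(default 10) times with seeds `base + 1 … base + n`; the per-sample mean
of the 10 bad-sample masks is computed and the repetition whose mask has
the smallest L1 distance to that mean is kept (ties go to the lowest
repetition index). Finally the cleaned continuous data are cut into 2-s
epochs with 50% overlap; an epoch is dropped when a discontinuity
boundary falls strictly inside its half-open sample interval.

## Feature extraction

* **Power spectrum** — Slepian multitaper per epoch between 1 and 100 Hz
  with ±1 Hz half-bandwidth (time–bandwidth 2, three tapers on a 2-s
  epoch), averaged over tapers, epochs and channels. Epochs are
  zero-padded to `pad_to_s` = 10 s so the grid step is 0.1 Hz and the
  band edges 7.9/12.9/30.1 Hz are representable; a 5-s pad would give a
  0.2 Hz grid on which they are not, which is why 10 s is the default
  while the unpadded native resolution of a 2-s epoch remains 0.5 Hz.
* **Alpha peak frequency** — the highest strict local maximum of the
  global spectrum inside 8–12.9 Hz (absent when the spectrum is monotone
  there, reported as `NA`), and the center of gravity
  Σ f·P(f) / Σ P(f) over the same band.
* **Source reconstruction** — band-specific array-gain LCMV beamformer
  onto the centroids of a 100-ROI source model. The sensor covariance of
  the band-pass-filtered epochs is regularized by 5% of its mean
  eigenvalue (`C + 0.05·tr(C)/n·I`). Each ROI's channels × 3 gain matrix
  is normalized to unit Frobenius norm (the array-gain convention):
  without this, locations with weak gains receive blown-up weights and
  their noise dominates the source-power map. The dipole orientation is
  fixed at the dominant eigenvector of the filtered output covariance
  (maximum-variance direction; sign fixed by making the first nonzero
  component positive), and the resulting 1-D filter has unit gain on the
  normalized lead field.
* **Functional connectivity** — between all 4950 unordered ROI pairs of
  the band-limited virtual time series. dwPLI uses one Hann taper per
  epoch on a 0.5 Hz grid (epochs are zero-padded to an even number of
  seconds so the grid is exact; a band edge off the grid is truncated to
  the highest bin at or below it, e.g. alpha ends at 12.5), epochs as the
  observation unit, and the debiased estimator
  `[(Σᵢ Im Xᵢ)² − Σᵢ (Im Xᵢ)²] / [(Σᵢ |Im Xᵢ|)² − Σᵢ (Im Xᵢ)²]`
  averaged over the band's bins; small negative values of the debiased
  estimator are kept. AEC orthogonalizes the per-epoch analytic signal of
  each member of a pair with respect to the other
  (`A⊥B = Im(A·conj(B)/|B|)`), correlates `|A⊥B|` with `|B|`, averages
  the two directions and then the epochs; a degenerate (zero-variance)
  orthogonalized envelope yields 0. The Hilbert transform is taken per
  epoch after a 10% cosine edge taper. Both measures are insensitive to
  zero-lag mixing, which is the reason they are computed in source space.
* **Graph metrics** — connectivity matrices are binarized by keeping the
  20% strongest connections (ceiling of density × 4950 edges; ties broken
  by row/column order; negative dwPLI values rank below positive ones —
  the rule is rank-based, hence invariant to monotone transforms).
  Reported are nodal degree and clustering, global clustering (mean nodal
  clustering), global efficiency (mean inverse shortest path length,
  unreachable pairs contributing 0), and smallworldness
  σ = (C/C_null)/(L/L_null) with L the characteristic path length of the
  largest component (required to cover ≥ 90% of nodes) and the null
  values means over 10 degree-preserving edge-swap rewirings (20·|E|
  attempted swaps, seeded). Shortest paths and rewiring use igraph.

## Group statistics

The dependent-samples cluster-based permutation test across frequencies
forms clusters of adjacent bins whose two-sided parametric p falls below
the cluster threshold (0.05), with sign-consistent membership; the
cluster statistic is the sum of t values, the null distribution is the
maximum absolute cluster statistic over 500 sign-flip (or label-shuffle)
randomizations, and the Monte-Carlo p is `(b + 1)/(n + 1)` — guaranteed
positive, with floor 1/501 ≈ 0.002 at 500 randomizations. When the test
is applied to power spectra, the spectra enter on the log scale: EEG
power is multiplicative across subjects (amplitude factors, impedances),
so raw-power paired differences are heavy-tailed and their sign-flip
null occasionally produces very large clusters, while log-power
differences are homoscedastic and a ratio effect becomes an additive,
near-homogeneous shift. Under the null the test is exactly calibrated
either way (the permutation guarantee does not depend on the scale);
the choice affects power, not validity. The JZS
Bayes-factor t-test integrates the noncentral-t likelihood against a
Cauchy prior on the standardized effect (scale √2/2 by default) by
adaptive quadrature; the mass-univariate driver loops it over the 4950
unordered ROI pairs of connectivity matrices.

## The synthetic-EEG generator

The generator is the package's test bed and defines the conditions under
which every detector and estimator is validated:

* sources are band-limited stochastic oscillators — complex Gaussian
  noise spectrally shaped around a center frequency (FWHM = bandwidth) —
  placed at atlas centroids and projected through the forward model with
  radial orientation, scaled so `amp` is the µV standard deviation at the
  peak electrode;
* phase-lag coupling shares the analytic carrier with a fixed phase
  shift, envelope coupling multiplies both carriers by a shared
  log-normal slow modulator;
* the background is 1/f^1.7 noise (a typical resting spectral exponent)
  from 24 random ROI sources projected through the same lead field, plus
  1 µV independent white sensor noise. Projecting the background through
  the head model is essential realism: per-channel independent noise has
  no spatial correlation, which no physiological field has, and it breaks
  any spatial-consistency criterion;
* the default montage has 26 electrodes (clinical-resolution cap),
  sampling at 250 Hz;
* artifacts are injected with their realized sample ranges recorded in a
  manifest: zeroed flat spans, 10× white-noise channels, 0.5-s blink
  bumps with a smooth Gaussian falloff from an inter-eye point (≈0.7 of
  the VEOG amplitude at frontopolar sites, ≈0.1–0.2 centrally) mirrored
  on an added VEOG channel, pure line-frequency sinusoids, and 500 µV
  broadband bursts across all channels.

The paired eyes-closed/eyes-open generator gives every subject two
recordings identical in configuration except that alpha-band source
amplitudes are multiplied by `alpha_ratio` (default 0.5) in the open
condition; its default source layout is a strong bilateral occipital
alpha rhythm (two sources at 25 µV), the regime in which the classic
alpha-blocking effect dominates the channel-averaged spectrum, with
log-normal inter-subject amplitude variability and per-subject seeds.

What the generator does **not** emulate: non-stationary drowsiness
cycles, heterogeneous electrode impedances, cap-position variability,
realistic skull anisotropy (the forward model is a 3-shell concentric
sphere), muscle-tone gradients, or the heavy-tailed artifact zoo of
clinical data. Passing tests therefore demonstrate correctness of the
algorithms under controlled physiology-like conditions, not expected
performance on any particular real dataset.

## Forward model

The packaged source model is a **synthetic** 100-centroid table
(`atlas100_synthetic.tsv`) on a cortical shell with the seven canonical
network labels; it reproduces the shape and interface of a 100-parcel /
7-network cortical parcellation without redistributing one, and any TSV
with columns `roi_index, roi_name, network, x, y, z` can replace it. The
analytic forward solution is a 3-shell concentric sphere
(brain/skull/scalp conductivities 0.33/0.0042/0.33 S/m, radii 0.87/0.92/1
of the scalp radius fit to the electrode cloud) evaluated by a 60-term
Legendre series whose per-degree radial coefficients come from the 5×5
interface linear system, solved in radius-normalized units for numerical
conditioning. A user-supplied lead field (HDF5, dataset `leadfield` of
shape ROI × channel × 3 with `channel_names`) is accepted for realistic
geometry.

## Numerical choices and degenerate inputs

* Sample indexing is 0-based with half-open `[start, end)` intervals; a
  boundary at index b means a break between samples b−1 and b, and an
  epoch is rejected iff a boundary falls strictly inside it.
* FIR orders follow the Hamming rule 3.3/Δf; epoch-level band-passes cap
  the order below the (reflect-padded) epoch length.
* The flat-run threshold (1e-8 µV) is far below amplifier quantization,
  so only true constant runs trigger it.
* ICA non-convergence (weight change above threshold at the step cap)
  raises an error with diagnostics rather than returning a partial
  decomposition; the repetition index is attached when it happens inside
  the stabilization loop.
* Proportional thresholding refuses an all-equal matrix (the threshold
  would be undefined); the Bayes-factor test refuses zero pooled
  variance; the center-of-gravity APF refuses an all-zero alpha band,
  while a merely peakless spectrum returns `NA` for the peak-maximum APF.
* All stochastic steps (bad-channel subsets, ICA, graph rewiring,
  permutations, simulation) draw from locally seeded RNG streams that
  restore the caller's RNG state, so the whole chain is reproducible
  from the parameter set.

## Problem sizes used in the shipped tests

The shipped test suite and the acceptance script validate on synthetic
recordings of 40–120 s at 250 Hz with 19–32 channels, 30-subject paired
datasets of 60-s recordings, 200-repetition null calibrations of the
cluster test at 500 randomizations each, and 100-run power checks of the
Bayes factor — sizes chosen so the full suite exercises every stage,
including the 10-repetition stabilization, in a few minutes on one core.
The mask-stabilization property is asserted with 3 repetitions (the
argmin property is dimension-free); the default of 10 repetitions is
exercised unchanged through `preprocess_recording` defaults in the
examples above.

## Known limitations

* The heuristic IC scorer is a transparent stand-in behind the same
  7-class interface as trained classifiers; its Muscle/Heart scores in
  particular are cruder than a trained model, and strong broadband
  bursts present during ICA can prevent a clean blink decomposition (the
  segment-removal stage, which runs afterwards, is the backstop — and is
  itself one reason the repetition-stabilization exists).
* The spherical head model misplaces sources relative to realistic
  BEM/FEM geometry; with ~26 electrodes, localization of a centroid
  source is only accurate to roughly one centroid spacing (the tests use
  32 channels for exact top-ROI recovery).
* dwPLI band averages quantize band edges to the 0.5 Hz grid.
* EDF support covers continuous equal-rate signals only.
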