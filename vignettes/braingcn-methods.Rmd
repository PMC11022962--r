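---
title: "Classifying depression from resting-state EEG with a brain-network GCN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying depression from resting-state EEG with a brain-network GCN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braingcn)
```

## The problem and the model

Depressed and non-depressed individuals differ both in the *spectral
content* of resting-state EEG (notably elevated low-frequency power) and in
the *spatial coupling* between recording sites. This package implements a
classifier that uses both: per-channel time–frequency complexity features
feed a recurrent encoder, and a functional-connectivity graph over the
channels drives a graph convolutional network (GCN).

The pipeline, per subject:

1. **Preprocessing.** A 50 Hz notch (biquad, Q = 30), a broad 0.3–50 Hz
   bandpass and an order-4 Butterworth 1–50 Hz bandpass are applied as a
   cascade, all zero-phase (forward–backward), so no stage introduces group
   delay that would smear segment boundaries. The per-channel mean of the
   first 120 s is subtracted (DC / drift removal). The recording is cut
   into 4-s windows with a 2-s stride (50% overlap); a 122-s recording
   yields `floor((122 - 4)/2) + 1 = 60` windows.
2. **Features.** Each window is decomposed into delta (0.5–4), theta
   (4–8), alpha (8–12) and beta (12–30 Hz) with order-4 Butterworth band
   filters, split into `t = 4` one-second sub-windows, and each
   (channel, sub-window, band) cell is summarised by differential entropy
   (DE). For a zero-mean Gaussian band-limited signal,
   `DE = 0.5 * log(2 * pi * e * sigma^2)`; we use the unbiased sample
   variance of the band-filtered sub-window. A `"literal"` variant,
   `0.5*log(P) + 0.5*log(2*pi*e*N)` with `P` the mean band power and `N`
   the sub-window length, is available behind a flag; the closed form is
   the default because it is the established DE definition and is testable
   against theory. Features are z-scored per (channel, band) with
   statistics fitted on training data only.
3. **Node encoding.** One shared-weight bidirectional LSTM runs over each
   channel's length-4, 4-band DE sequence; the concatenated final forward
   and backward hidden states give node features `H` (channels × 2·hidden).
4. **Brain network.** The adjacency `A` is the Pearson correlation matrix
   of the channels, computed from the concatenated preprocessed recordings
   of the *training-fold subjects only*. The GCN propagation matrix is
   `S = D^{-1/2}(A' + I)D^{-1/2}` with `A'` the off-diagonal adjacency
   after a signed-edge policy and `D` the degree matrix with self-loops.
5. **GCN classifier.** Two blocks of graph convolution
   (`H <- act(S H W + b)`), bounded-ReLU activation
   (`min(max(x, 0), 6)`), and 50% pooling; then dropout (rate 0.5), a
   dense layer and softmax over {control, depressed}. The loss is mean
   cross-entropy plus `lambda`(default 1e-4) times the sum of squared
   weights *and biases*.

## Design choices where the design was open

- **Two overlapping bandpass stages.** The preprocessing convention we
  follow names both a 0.3–50 Hz bandpass and a 1–50 Hz Butterworth; we
  apply both, in that order, as a cascade (composite passband effectively
  1–50 Hz). Either stage can be disabled in `filter_spec()`.
- **Signed edges.** Pearson correlations can be negative, which would make
  degree normalisation ill-defined. Default policy: absolute value
  (preserves coupling *strength*); `clip_negative` is available.
- **Pooling scheme.** "50% spectral pooling" is realised as graph
  coarsening by greedy heavy-edge matching on the (policy-transformed)
  adjacency: the strongest-correlated unmatched pair merges first, ties
  break to the lowest index, leftover nodes pair by index, a final odd
  node stays a singleton — so level k has exactly `ceiling(n / 2^k)`
  nodes and the assignment is an exact partition. Coarse edge weights are
  sums of fine weights between groups; pooled node features are
  elementwise maxima (mean available). A graph-Fourier-truncation reading
  of "spectral pooling" exists; we follow the halving-node-count reading
  because the node count (64 → 32 → 16) is the stated behaviour.
- **Sub-window count `t`.** Not fixed by convention; we use 4 non-
  overlapping 1-s sub-windows per 4-s window — 1-s resolution is the
  common DE convention and divides the window evenly.
- **Architecture defaults.** Hidden 16 per LSTM direction (node dimension
  32), GCN widths [32, 64] matching the two pooling steps, flattened
  readout into the dense head, dropout after the last pooling. The
  smallest architecture consistent with the two-level pooling design.
- **Bounded ReLU.** `min(max(x, 0), cap)` with cap 6 (configurable); the
  bipolar-ReLU reading of "BReLU" was considered and rejected as the less
  common usage.
- **Loss regularisation.** The L2 term includes biases as well as weights.
- **Checkpoint selection.** Training runs a fixed epoch budget; an inner
  subject-wise 90/10 split of the training subjects (stratified by class,
  so the monitor set always contains both classes when it can) tracks
  per-epoch accuracy, and the best-monitor checkpoint is kept. No early
  stopping rule is invented.
- **Class weighting at small cohort sizes.** With ~20 subjects,
  leave-subjects-out folds swing the training class prior fold to fold,
  and an unweighted fit on weakly informative data drifts toward the
  training majority class — which is systematically the *opposite* of a
  pure-class validation fold, biasing accuracy on label-free data well
  below chance ("anti-learning"). The scaled-down preset
  (`train_preset()`) therefore weights the cross-entropy by inverse class
  frequency, so chance-level data scores at chance; the full-scale
  default (`train_config()`) leaves weighting off.
- **Learning rate of the scaled-down preset.** The full-data defaults
  (100 epochs, batch 512, Adam 1e-5) suit thousands of segments; at a few
  hundred segments and 20 epochs that step size cannot move the loss.
  `train_preset()` uses Adam 1e-3, a conventional step size at this scale,
  chosen once as the package's small-study default.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` produces two-class multichannel recordings with
exactly the structure the classifier exploits:

- per-band Gaussian noise, band-limited by the *same* order-4 Butterworth
  filters the feature extractor uses (simulator and pipeline stay
  spectrally consistent), with a 1/f-like base power profile
  (delta 1, theta 0.8, alpha 0.6, beta 0.4, relative units);
- a class effect: depressed-class delta and theta power multiplied by
  `1 + effect_size` (low-frequency elevation); `effect_size = 0` makes
  the classes distributionally identical;
- community-structured correlation: channels are assigned round-robin to
  communities (default 4) and share a latent band-limited component with
  weight `sqrt(rho)`, giving within-community correlation ≈ `rho` by
  construction (always a valid covariance for `rho` in [0, 1));
- optional common-mode 50 Hz line contamination.

Defaults mirror the resting-state acquisition geometry of the public
depression EEG cohorts the method targets: 64 channels, 250 Hz, 122 s,
24 depressed / 29 controls. Presets: `easy` (effect 2), `hard` (0.5),
`null` (0), each 16 channels, 30 s, 10 + 10 subjects.

The generator does **not** emulate: 1/f continuum spectra within bands,
non-Gaussian transients (eye blinks, muscle), volume-conduction geometry,
nonstationarity, or subject-level heterogeneity beyond the sampled noise.
Passing tests on this generator therefore demonstrate that the pipeline
recovers class structure *of the kind it models* without subject leakage —
not clinical-grade performance on real EEG.

## Numerical choices and degenerate inputs

- Zero-phase filtering throughout (`signal::filtfilt`); the 50 Hz notch is
  a hand-computed RBJ biquad (Q = 30) since no notch designer ships with
  the filtering library.
- DE of a constant (zero-variance) signal raises an error rather than
  silently propagating `-Inf`; the same for zero-power inputs to the log
  band-power feature and zero-spread features in the normaliser.
- Softmax is computed with max-subtraction; `log(0)` in the loss is
  guarded by clamping probabilities at 1e-12.
- Gradients are exact analytic backpropagation (through the BiLSTM, graph
  convolutions, bounded ReLU, max pooling and dropout mask); a
  finite-difference check in the test suite verifies them to <1e-3
  relative error. Optimisation is standard bias-corrected Adam.
- Recordings shorter than one window yield an empty segment list with a
  warning (batch runs skip short files); zero-padding is refused because
  it would distort DE estimates.
- All randomness (initialisation, shuffling, dropout, simulation) is
  driven by explicit seeds; a rerun with the same seed reproduces
  per-fold metrics exactly.

## Problem sizes used in the shipped checks

The package's own quantitative checks run on deliberately small problems:
segment accounting uses 2-channel, 122-s synthetic recordings (53 and 119
subjects; channel count does not enter the count); the DE closed-form
check uses 200 replicates of 1,000 samples; and the cross-validation
checks use the `easy` and `null` presets (20 subjects, 16 channels, 30 s,
reduced model: hidden 8, 20 epochs, batch 64) — sizes at which the full
pipeline runs in minutes on one core while still exercising every stage.
Baseline correction is skipped for the 30-s presets (the recordings are
shorter than the 120-s convention; the band filters already remove DC).

## Known limitations

- Which 64 of a 128-channel montage to use is acquisition-specific; the
  channel subset is a required input for high-density montages, never
  guessed.
- EDF input is not supported in this build; recordings are read from the
  plain-text matrix + JSON sidecar format (`read_recording()`).
- Artifact removal is a hook (`remove_artifacts()`) for an external
  ICA-based cleaner; no decomposition is performed internally.
- The GCN adjacency is fixed per fold (training subjects only); learned
  or attention-weighted adjacencies are out of scope.
- Metrics with empty denominators (e.g. precision with no positive
  predictions) are reported as `NaN` and excluded from fold averages.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_preset("easy", seed = 11))
ds  <- build_dataset(sim$recordings, baseline_s = NULL)
cv  <- cross_validate(ds,
                      model_config(bilstm_hidden = 8),
                      train_preset(seed = 42, k_folds = 10))
cv$summary
```
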