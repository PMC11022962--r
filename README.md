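# braingcn

Two-class (depressed vs. control) classification of multichannel
resting-state EEG, combining per-channel time–frequency complexity with the
spatial topology of inter-channel coupling. Intended for researchers
evaluating EEG biomarkers of depression and, more generally, for anyone who
needs a leakage-careful subject-wise classification pipeline over
correlation brain networks.

## The method

For each subject the pipeline:

1. **Preprocesses** the recording: 50 Hz notch (biquad, Q = 30), 0.3–50 Hz
   bandpass, order-4 Butterworth 1–50 Hz bandpass — all zero-phase — then
   subtracts the per-channel mean of the first 120 s, and cuts 4-s windows
   with 2-s stride (50% overlap).
2. **Extracts features**: each window is decomposed into delta/theta/
   alpha/beta with order-4 Butterworth band filters and summarised per
   1-s sub-window by differential entropy,
   `DE = ½ ln(2πe σ²)` (Gaussian closed form, unbiased sample variance),
   giving a tensor `X ∈ R^{n×t×d}` (channels × sub-windows × bands),
   z-scored with training-fold statistics.
3. **Encodes nodes**: a shared-weight BiLSTM reads each channel's band
   sequence; `H = BiLSTM(X) ∈ R^{n×d'}` concatenates final forward and
   backward hidden states.
4. **Builds the brain network**: `A[i,j] = Pearson r` between channels i
   and j, estimated from training-fold subjects only; the propagation
   matrix is `S = D̃^{-1/2} Ã D̃^{-1/2}` with `Ã = |A|_offdiag + I`.
5. **Classifies** with a GCN: two blocks of
   `H ← BReLU(S H W + b)` followed by 50% graph coarsening
   (greedy heavy-edge matching, max-pooled features), then dropout, a
   dense layer and softmax; loss = cross-entropy + λ‖θ‖².

Evaluation is subject-wise 10-fold cross-validation (no subject on both
sides of a fold) with accuracy, precision, sensitivity, specificity and F1
from the per-fold confusion matrix.

A synthetic EEG generator (`simulate_dataset()`) provides two-class
recordings with class-dependent low-frequency power and
community-structured inter-channel correlation, so the whole pipeline is
testable without any data download.

## Worked example

```r
library(braingcn)

sim <- simulate_dataset(sim_preset("easy", seed = 11))  # 20 subjects, 16 ch, 30 s
ds  <- build_dataset(sim$recordings, baseline_s = NULL)
ds
#> <eeg_dataset> 20 subjects (10 depressed), 280 segments

cv <- cross_validate(ds,
                     model_config(bilstm_hidden = 8),
                     train_preset(seed = 42, k_folds = 10))
cv
#> <cv_result> 10 folds
#>       metric mean sd
#>     accuracy    1  0
#>    precision    1  0
#>  sensitivity    1  0
#>  specificity    1  0
#>           f1    1  0
```

Each fold holds out 2 subjects (28 segments); mean accuracy 1.0 says
the classifier almost perfectly recovers the simulated class effect
(doubled-to-tripled delta/theta power) on subjects it never saw. On the
`"null"` preset (no class effect) the same protocol stays at chance
(~0.5), confirming there is no subject or fold leakage.

A thin CLI wraps the same functions:

```sh
exec/braingcn simulate --preset easy --out sim_data --seed 11
exec/braingcn cv --input sim_data --out metrics.json --seed 42
```

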