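# Shared fixtures: small deterministic recordings and sine generators.

make_sine_recording <- function(freq_hz, fs = 250, duration_s = 10,
                                n_channels = 2, amplitude = 1,
                                label = 0L, subject_id = "sine") {
  tt <- (seq_len(round(fs * duration_s)) - 1) / fs
  data <- matrix(rep(amplitude * sin(2 * pi * freq_hz * tt),
                     each = n_channels),
                 nrow = n_channels)
  eeg_recording(data, fs, sprintf("ch%02d", seq_len(n_channels)),
                subject_id, label)
}

make_noise_recording <- function(seed = 1, fs = 250, duration_s = 10,
                                 n_channels = 4, label = 0L,
                                 subject_id = "noise") {
  set.seed(seed)
  data <- matrix(rnorm(n_channels * round(fs * duration_s)),
                 nrow = n_channels)
  eeg_recording(data, fs, sprintf("ch%02d", seq_len(n_channels)),
                subject_id, label)
}

make_noise_segment <- function(seed = 1, fs = 250, window_s = 4,
                               n_channels = 4) {
  rec <- make_noise_recording(seed, fs, window_s, n_channels)
  segment_recording(rec, window_s, window_s)[[1]]
}

# Brute-force Pearson correlation straight from the sum formula.
pearson_oracle <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sum((x - xm) * (y - ym)) /
    sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}

# Naive triple-loop sigma(S H W) oracle.
gcn_oracle <- function(S, H, W, activation = identity) {
  n <- nrow(S); dout <- ncol(W)
  out <- matrix(0, n, dout)
  SH <- matrix(0, n, ncol(H))
  for (i in seq_len(n))
    for (k in seq_len(ncol(H)))
      for (j in seq_len(n))
        SH[i, k] <- SH[i, k] + S[i, j] * H[j, k]
  for (i in seq_len(n))
    for (k in seq_len(dout))
      for (j in seq_len(ncol(H)))
        out[i, k] <- out[i, k] + SH[i, j] * W[j, k]
  activation(out)
}

# Sample-by-sample sliding-window enumerator (segment-count oracle).
count_windows_bruteforce <- function(n_samples, fs, window_s, stride_s) {
  ws <- round(window_s * fs)
  step <- round(stride_s * fs)
  count <- 0L
  start <- 0L
  while (start + ws <= n_samples) {
    count <- count + 1L
    start <- start + step
  }
  count
}
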