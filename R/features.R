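#' Canonical EEG frequency bands
#'
#' The four rhythms used throughout: delta 0.5--4 Hz, theta 4--8 Hz,
#' alpha 8--12 Hz, beta 12--30 Hz.
#'
#' @return Named list of `c(low_hz, high_hz)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

# One order-`order` Butterworth bandpass, zero-phase, applied to matrix rows.
.band_filter_rows <- function(data, band, fs, order = 4) {
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band [", band[1], ", ", band[2],
         "] Hz must lie strictly inside (0, ", fs / 2, ") Hz at fs = ", fs)
  bw <- signal::butter(order, band / (fs / 2), type = "pass")
  .filtfilt_rows(bw$b, bw$a, data)
}

#' Decompose a segment into frequency bands
#'
#' Applies an order-4 Butterworth bandpass per band, zero-phase, to every
#' channel.
#'
#' @param seg An `eeg_segment` (or `eeg_recording`).
#' @param bands Named list of band edges as from [eeg_bands()].
#' @param order Butterworth order.
#' @return Named list of channels x samples matrices, one per band.
#' @export
band_decompose <- function(seg, bands = eeg_bands(), order = 4) {
  fs <- seg$sampling_rate_hz
  lapply(bands, function(b) .band_filter_rows(seg$data, b, fs, order))
}

#' Differential entropy of a band-limited signal
#'
#' For an (approximately) Gaussian band-limited signal, differential
#' entropy has the closed form 1/2 log(2*pi*e*sigma^2); this is the default
#' (`variant = "gaussian_closed_form"`, with sigma^2 the unbiased sample
#' variance). The alternative `"literal"` variant computes
#' 1/2 log(P) + 1/2 log(2*pi*e*N) with P the mean band power and N the
#' sub-window length in samples; it differs by an additive constant when
#' the signal is zero-mean.
#'
#' @param x Numeric vector (band-filtered sub-window), length >= 2.
#' @param variant `"gaussian_closed_form"` or `"literal"`.
#' @return Differential entropy in nats (finite real).
#' @export
differential_entropy <- function(x, variant = c("gaussian_closed_form",
                                                "literal")) {
  variant <- match.arg(variant)
  if (length(x) < 2L) stop("need at least 2 samples")
  if (variant == "gaussian_closed_form") {
    v <- stats::var(x)
    if (!is.finite(v) || v <= 0)
      stop("degenerate (zero-variance) signal: differential entropy undefined")
    0.5 * log(2 * pi * exp(1) * v)
  } else {
    p <- mean(x^2)
    if (!is.finite(p) || p <= 0)
      stop("degenerate (zero-power) signal: differential entropy undefined")
    0.5 * log(p) + 0.5 * log(2 * pi * exp(1) * length(x))
  }
}

#' Log band-power feature
#'
#' Log of the mean squared amplitude of a band-filtered sub-window; the
#' spectral-power alternative to differential entropy.
#'
#' @param x Numeric vector.
#' @return log mean power (finite real).
#' @export
psd_feature <- function(x) {
  p <- mean(x^2)
  if (!is.finite(p) || p <= 0)
    stop("degenerate (zero-power) signal: log band power undefined")
  log(p)
}

#' Build the channels x time x bands feature tensor of one segment
#'
#' The segment is band-decomposed, each band signal is split into
#' `t_subwindows` equal non-overlapping sub-windows, and each
#' (channel, sub-window, band) cell is summarised by differential entropy
#' (default) or log band power. With the default 4-s window and
#' `t_subwindows = 4` each cell covers one second.
#'
#' @param seg An `eeg_segment`.
#' @param bands Band list as from [eeg_bands()].
#' @param t_subwindows Number of equal sub-windows (the BiLSTM sequence
#'   length).
#' @param feature_kind `"DE"` or `"PSD"`.
#' @param de_variant Passed to [differential_entropy()].
#' @return A `feature_tensor`: numeric array `(channels, t, bands)` with
#'   attributes `subject_id`, `label`, `feature_kind`, `band_names`,
#'   `channel_names`.
#' @export
build_feature_tensor <- function(seg, bands = eeg_bands(), t_subwindows = 4,
                                 feature_kind = c("DE", "PSD"),
                                 de_variant = "gaussian_closed_form") {
  feature_kind <- match.arg(feature_kind)
  ws <- ncol(seg$data)
  if (ws %% t_subwindows != 0L) {
    divs <- Filter(function(t) ws %% t == 0L, seq_len(min(ws, 32L)))
    stop("segment length ", ws, " samples is not divisible into ",
         t_subwindows, " equal sub-windows; valid choices include: ",
         paste(divs, collapse = ", "))
  }
  sub_len <- ws %/% t_subwindows
  per_band <- band_decompose(seg, bands)
  n <- nrow(seg$data)
  vals <- array(NA_real_, dim = c(n, t_subwindows, length(bands)))
  for (b in seq_along(bands)) {
    sig <- per_band[[b]]
    for (j in seq_len(t_subwindows)) {
      cols <- (j - 1L) * sub_len + seq_len(sub_len)
      for (c in seq_len(n)) {
        x <- sig[c, cols]
        vals[c, j, b] <- if (feature_kind == "DE")
          differential_entropy(x, de_variant) else psd_feature(x)
      }
    }
  }
  structure(vals, class = "feature_tensor",
            subject_id = seg$subject_id, label = seg$label,
            feature_kind = feature_kind, band_names = names(bands),
            channel_names = rownames(seg$data))
}

#' Feature tensors for a list of segments
#' @param segments List of `eeg_segment`s.
#' @param ... Passed to [build_feature_tensor()].
#' @return List of `feature_tensor`s.
#' @export
build_feature_tensors <- function(segments, ...) {
  lapply(segments, build_feature_tensor, ...)
}

#' Fit per-(channel, band) z-score statistics on training tensors
#'
#' Means and standard deviations are pooled over segments and sub-windows,
#' separately for every (channel, band) cell. Fit on training data only and
#' reuse the returned stats on held-out data to avoid leakage.
#'
#' @param tensors List of `feature_tensor`s (training set).
#' @return A `norm_stats` object with `mean` and `sd` matrices
#'   (channels x bands).
#' @export
fit_normalizer <- function(tensors) {
  stopifnot(length(tensors) >= 1L)
  d <- dim(tensors[[1]])
  # stack to (channels, bands, segments*t)
  big <- vapply(tensors, identity, array(0, dim = d))       # (n, t, d, B)
  n <- d[1]; nb <- d[3]
  mu <- matrix(0, n, nb); sd_ <- matrix(0, n, nb)
  for (b in seq_len(nb)) {
    slab <- big[, , b, , drop = FALSE]                      # (n, t, 1, B)
    m <- matrix(slab, nrow = n)                             # n x (t*B)
    mu[, b] <- rowMeans(m)
    sd_[, b] <- apply(m, 1, stats::sd)
  }
  bad <- which(sd_ <= 0 | !is.finite(sd_), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("degenerate (zero spread) feature at channel ", bad[1, 1],
         ", band ", bad[1, 2],
         "; cannot z-score (need > 1 distinct value)")
  structure(list(mean = mu, sd = sd_), class = "norm_stats")
}

#' Apply z-score normalisation to a feature tensor
#'
#' Uses statistics from [fit_normalizer()]; applying twice with the same
#' stats is not an identity (the second pass re-centres already-scaled
#' values).
#'
#' @param tensor A `feature_tensor`.
#' @param stats A `norm_stats` object.
#' @return The normalised `feature_tensor`.
#' @export
apply_normalizer <- function(tensor, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  d <- dim(tensor)
  out <- tensor
  for (b in seq_len(d[3]))
    out[, , b] <- (tensor[, , b] - stats$mean[, b]) / stats$sd[, b]
  out
}
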