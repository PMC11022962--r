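#' Filtering specification for EEG preprocessing
#'
#' Defaults follow common clinical-EEG practice: a 50 Hz power-line notch,
#' a broad 0.3--50 Hz bandpass, then an order-4 Butterworth 1--50 Hz
#' bandpass. The two bandpass stages are applied as a cascade (composite
#' passband effectively 1--50 Hz); either stage can be disabled by setting
#' its bounds to `NULL`.
#'
#' @param notch_hz Power-line notch frequency (NULL disables).
#' @param notch_q Quality factor of the notch biquad.
#' @param bandpass_low_hz,bandpass_high_hz Broad bandpass edges (Hz).
#' @param butter_low_hz,butter_high_hz Butterworth bandpass edges (Hz).
#' @param butter_order Butterworth order for both bandpass stages.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(notch_hz = 50, notch_q = 30,
                        bandpass_low_hz = 0.3, bandpass_high_hz = 50,
                        butter_low_hz = 1, butter_high_hz = 50,
                        butter_order = 4) {
  chk <- function(lo, hi, what) {
    if (is.null(lo) != is.null(hi))
      stop(what, ": both edges must be given or both NULL")
    if (!is.null(lo) && !(lo > 0 && lo < hi))
      stop(what, ": need 0 < low < high, got [", lo, ", ", hi, "]")
  }
  chk(bandpass_low_hz, bandpass_high_hz, "bandpass")
  chk(butter_low_hz, butter_high_hz, "butterworth")
  structure(list(notch_hz = notch_hz, notch_q = notch_q,
                 bandpass_low_hz = bandpass_low_hz,
                 bandpass_high_hz = bandpass_high_hz,
                 butter_low_hz = butter_low_hz,
                 butter_high_hz = butter_high_hz,
                 butter_order = as.integer(butter_order)),
            class = "filter_spec")
}

# RBJ-cookbook notch biquad (the signal package has no notch designer).
.notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase (forward-backward) filtering of each matrix row.
.filtfilt_rows <- function(b, a, data) {
  out <- data
  for (i in seq_len(nrow(data))) out[i, ] <- signal::filtfilt(b, a, data[i, ])
  out
}

.check_nyquist <- function(hz, fs, what) {
  if (hz >= fs / 2)
    stop("invalid filter parameter: ", what, " = ", hz,
         " Hz is at or above the Nyquist frequency ", fs / 2, " Hz")
}

#' Apply notch and bandpass filtering to a recording
#'
#' Runs the `filter_spec` cascade: 50 Hz notch biquad, then the broad
#' bandpass, then the order-4 Butterworth bandpass, all applied
#' forward-backward (zero phase) so segment-level features are not
#' time-shifted.
#'
#' @param rec An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered `eeg_recording` (same shape).
#' @export
apply_filters <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  fs <- rec$sampling_rate_hz
  data <- rec$data
  if (!is.null(spec$notch_hz)) {
    .check_nyquist(spec$notch_hz, fs, "notch frequency")
    nc <- .notch_coefs(spec$notch_hz, fs, spec$notch_q)
    data <- .filtfilt_rows(nc$b, nc$a, data)
  }
  for (stage in list(c(spec$bandpass_low_hz, spec$bandpass_high_hz),
                     c(spec$butter_low_hz, spec$butter_high_hz))) {
    if (is.null(stage) || length(stage) == 0L) next
    .check_nyquist(stage[2], fs, "bandpass high cut")
    bw <- signal::butter(spec$butter_order, stage / (fs / 2), type = "pass")
    data <- .filtfilt_rows(bw$b, bw$a, data)
  }
  out <- rec
  out$data <- data
  out
}

#' Baseline-correct a recording
#'
#' Subtracts, per channel, the mean of the first `baseline_s` seconds from
#' the whole channel, removing DC offset so the baseline window of the
#' output has zero mean.
#'
#' @param rec An `eeg_recording`.
#' @param baseline_s Baseline window length in seconds (default 120, the
#'   first two minutes).
#' @return The corrected `eeg_recording`.
#' @export
baseline_correct <- function(rec, baseline_s = 120) {
  stopifnot(inherits(rec, "eeg_recording"))
  nb <- round(baseline_s * rec$sampling_rate_hz)
  if (nb < 1L || nb > ncol(rec$data))
    stop("recording (", signif(recording_duration(rec), 4),
         " s) is shorter than the baseline window (", baseline_s,
         " s); pass a smaller baseline_s")
  mu <- rowMeans(rec$data[, seq_len(nb), drop = FALSE])
  out <- rec
  out$data <- rec$data - mu
  out
}

#' Number of sliding windows that fit a recording
#' @param duration_s Recording duration (s).
#' @param window_s Window length (s).
#' @param stride_s Stride between window starts (s).
#' @return Integer segment count (0 if the window does not fit).
#' @export
n_segments <- function(duration_s, window_s = 4, stride_s = 2) {
  if (duration_s < window_s) return(0L)
  as.integer(floor((duration_s - window_s) / stride_s + 1e-9) + 1L)
}

#' Cut a recording into overlapping fixed-length segments
#'
#' Slides a `window_s`-second window with `stride_s`-second steps (defaults
#' 4 s / 2 s, i.e. 50% overlap). Each segment inherits the subject id and
#' label. Recordings shorter than one window yield an empty list with a
#' warning rather than an error, so batch runs skip short files.
#'
#' @param rec An `eeg_recording`.
#' @param window_s Window length in seconds.
#' @param stride_s Stride in seconds (> 0).
#' @return List of `eeg_segment` objects.
#' @export
segment_recording <- function(rec, window_s = 4, stride_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (stride_s <= 0) stop("stride_s must be > 0")
  fs <- rec$sampling_rate_hz
  ws <- round(window_s * fs)
  dur <- recording_duration(rec)
  n <- n_segments(dur, window_s, stride_s)
  if (n == 0L) {
    warning("recording ", rec$subject_id, " (", signif(dur, 4),
            " s) is shorter than the ", window_s, " s window; skipped")
    return(list())
  }
  lapply(seq_len(n) - 1L, function(k) {
    start <- round(k * stride_s * fs)
    structure(
      list(subject_id = rec$subject_id, label = rec$label,
           sampling_rate_hz = fs, start_time_s = start / fs,
           data = rec$data[, start + seq_len(ws), drop = FALSE]),
      class = "eeg_segment")
  })
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> subject %s, label %d, t0 = %g s, %d ch x %d samples\n",
              x$subject_id, x$label, x$start_time_s, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Select and reorder channels of a recording
#'
#' @param rec An `eeg_recording`.
#' @param subset Ordered character vector of channel names to keep; the
#'   output rows follow this order.
#' @return The reduced `eeg_recording`.
#' @export
select_channels <- function(rec, subset) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(subset, rec$channel_names)
  if (length(missing) > 0L)
    stop("channel(s) not present in recording: ",
         paste(missing, collapse = ", "))
  idx <- match(subset, rec$channel_names)
  out <- rec
  out$data <- rec$data[idx, , drop = FALSE]
  out$channel_names <- rec$channel_names[idx]
  out
}

#' Artifact-removal hook
#'
#' Artifact rejection (e.g. ICA-based ocular/muscle cleanup) is delegated:
#' `method = "none"` passes the recording through unchanged, while
#' `method = "external_ica"` invokes a user-supplied callable
#' (`fn(rec) -> rec`), whose output shape is validated. No decomposition is
#' performed by this package.
#'
#' @param rec An `eeg_recording`.
#' @param method `"none"` or `"external_ica"`.
#' @param fn Callable used when `method = "external_ica"`.
#' @return An `eeg_recording` of identical shape.
#' @export
remove_artifacts <- function(rec, method = c("none", "external_ica"),
                             fn = NULL) {
  method <- match.arg(method)
  if (method == "none") return(rec)
  if (!is.function(fn))
    stop("method = 'external_ica' requires a callable `fn(rec)`")
  out <- fn(rec)
  if (!inherits(out, "eeg_recording") ||
      !identical(dim(out$data), dim(rec$data)))
    stop("external artifact remover changed the recording shape: expected ",
         nrow(rec$data), " x ", ncol(rec$data))
  out
}

#' Full preprocessing chain for one recording
#'
#' Convenience wrapper: channel selection (optional), filtering, baseline
#' correction (optional) and segmentation.
#'
#' @param rec An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @param baseline_s Baseline window in seconds, or `NULL` to skip.
#' @param window_s,stride_s Segmentation parameters.
#' @param channels Optional channel subset (ordered names).
#' @return List with the preprocessed continuous `recording` and its
#'   `segments`.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(),
                                 baseline_s = 120,
                                 window_s = 4, stride_s = 2,
                                 channels = NULL) {
  if (!is.null(channels)) rec <- select_channels(rec, channels)
  rec <- apply_filters(rec, spec)
  if (!is.null(baseline_s)) rec <- baseline_correct(rec, baseline_s)
  list(recording = rec,
       segments = segment_recording(rec, window_s, stride_s))
}
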