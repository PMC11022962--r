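#' Construct a raw EEG recording
#'
#' A recording is one subject's continuous multichannel EEG: a numeric
#' channels x samples matrix (microvolts) plus the metadata the downstream
#' pipeline needs (sampling rate, ordered channel names, subject id and a
#' binary diagnosis label).
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate_hz Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector naming each row of `data`.
#' @param subject_id Subject identifier.
#' @param label Class label: 0 = control, 1 = depressed.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate_hz, channel_names = NULL,
                          subject_id = "s1", label = 0L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L) stop("recording needs at least one channel")
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(rownames(data))) rownames(data)
                     else sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nrow(data), ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive scalar")
  if (!label %in% c(0L, 1L))
    stop("label must be 0 (control) or 1 (depressed)")
  rownames(data) <- channel_names
  structure(
    list(subject_id = as.character(subject_id),
         label = as.integer(label),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         channel_names = as.character(channel_names),
         data = data),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, label %d, %d ch x %d samples (%.1f s @ %g Hz)\n",
              x$subject_id, x$label, nrow(x$data), ncol(x$data),
              recording_duration(x), x$sampling_rate_hz))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$sampling_rate_hz

#' Write a recording as a delimited matrix plus a JSON sidecar
#'
#' The on-disk format is plain text: `<subject_id>.tsv` holding the
#' channels x samples matrix (no header), and `<subject_id>.json` holding
#' `subject_id`, `label`, `sampling_rate_hz` and `channel_names`.
#'
#' @param rec An `eeg_recording`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the path of the matrix file.
#' @export
write_recording <- function(rec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, rec$subject_id)
  data.table::fwrite(data.table::as.data.table(rec$data),
                     paste0(stem, ".tsv"), sep = "\t", col.names = FALSE)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, label = rec$label,
         sampling_rate_hz = rec$sampling_rate_hz,
         channel_names = rec$channel_names),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(stem, ".tsv"))
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path to the `.tsv` matrix file (or its stem); the `.json`
#'   sidecar is looked up next to it.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path) {
  stem <- sub("\\.tsv$", "", path)
  mat_path <- paste0(stem, ".tsv")
  meta_path <- paste0(stem, ".json")
  if (!file.exists(mat_path)) stop("matrix file not found: ", mat_path)
  if (!file.exists(meta_path)) stop("sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  data <- as.matrix(data.table::fread(mat_path, header = FALSE, sep = "\t"))
  dimnames(data) <- NULL
  eeg_recording(data, meta$sampling_rate_hz, meta$channel_names,
                meta$subject_id, meta$label)
}

#' Read every recording in a directory
#' @param dir Directory containing `.tsv`/`.json` pairs.
#' @return List of `eeg_recording` objects.
#' @export
read_recordings <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no .tsv recordings found in ", dir)
  lapply(files, read_recording)
}
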