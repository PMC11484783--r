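#' The nine task/artifact labels
#'
#' Labels for the nine recorded task blocks. Four of them (eye blink, eye
#' movement, chewing, teeth clenching) are the kinds the denoiser is trained
#' and evaluated on; the rest pass through preprocessing but are excluded from
#' the default train/test manifest.
#'
#' @return character vector of the nine artifact kind labels.
#' @export
artifact_kinds <- function() {
  c("eye_blink", "eye_movement", "chewing", "clench_teeth",
    "swallowing", "tongue_movement", "jaw_movement", "head_movement",
    "shoulder_movement")
}

#' @rdname artifact_kinds
#' @export
evaluation_kinds <- function() {
  c("eye_blink", "eye_movement", "chewing", "clench_teeth")
}

#' Construct a multichannel EEG recording
#'
#' The central container everything is clipped from: a channels x samples
#' amplitude matrix (microvolts before normalization, dimensionless in
#' \[-1, 1\] after), a sampling rate, ordered channel labels, a subject id and
#' ordered block annotations.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one label per row of `data`.
#' @param subject_id subject identifier string.
#' @param annotations data.frame with columns `label` (an artifact kind or
#'   `"relax"`), `onset_s` and `duration_s` in seconds, ordered by onset.
#'   Consecutive blocks may share a 2-s relax flank; otherwise task blocks do
#'   not overlap.
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_names = NULL, subject_id = "sub1",
                      annotations = empty_annotations()) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  if (is.null(channel_names)) {
    channel_names <- default_channel_names(nrow(data))
  }
  rec <- structure(
    list(data = data, fs = fs, channel_names = channel_names,
         subject_id = subject_id, annotations = as_annotations(annotations)),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

#' @rdname recording
#' @export
empty_annotations <- function() {
  data.frame(label = character(0), onset_s = numeric(0),
             duration_s = numeric(0), stringsAsFactors = FALSE)
}

as_annotations <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  need <- c("label", "onset_s", "duration_s")
  if (!all(need %in% names(ann))) {
    eegdenoise_abort("annotations need columns label, onset_s, duration_s",
                     "eegdenoise_format_error")
  }
  ann[need]
}

#' Default 10-20 montage labels for n channels
#'
#' Standard 32-electrode 10-20/10-10 montage names, recycled with numeric
#' suffixes when more than 32 channels are requested.
#'
#' @param n number of channels.
#' @return character vector of length `n`.
#' @export
default_channel_names <- function(n) {
  base <- c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
            "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
            "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
            "PO3", "PO4", "O1", "Oz", "O2")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("EEG", seq_len(n - length(base))))
}

#' Validate a recording against its invariants
#'
#' Checks the row count matches the channel labels, the sampling rate is
#' positive and every annotation span lies within the recording.
#'
#' @param rec an `eeg_recording`.
#' @return `rec`, invisibly; errors otherwise.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) {
    eegdenoise_abort("not an eeg_recording", "eegdenoise_format_error")
  }
  if (nrow(rec$data) == 0L) {
    eegdenoise_abort("recording has zero channels", "eegdenoise_format_error")
  }
  if (nrow(rec$data) != length(rec$channel_names)) {
    eegdenoise_abort("data rows != number of channel names",
                     "eegdenoise_format_error")
  }
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0) {
    eegdenoise_abort("fs must be a positive scalar", "eegdenoise_config_error")
  }
  dur <- ncol(rec$data) / rec$fs
  ann <- rec$annotations
  if (nrow(ann)) {
    bad <- ann$onset_s < -1e-9 | (ann$onset_s + ann$duration_s) > dur + 1e-9
    if (any(bad)) {
      eegdenoise_abort("annotation span outside the recording",
                       "eegdenoise_range_error")
    }
    known <- c(artifact_kinds(), "relax")
    if (!all(ann$label %in% known)) {
      eegdenoise_abort("unknown annotation label", "eegdenoise_format_error")
    }
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s), %d annotations\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param rec an `eeg_recording`.
#' @return `n_samples`: integer sample count; `duration_s`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs
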