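#' Zero-phase band-pass filter a recording
#'
#' Butterworth band-pass applied forward-backward (zero phase) per channel,
#' preserving length. The default 0.5-40 Hz band keeps the main EEG rhythms
#' while suppressing baseline drift and line noise at 50/60 Hz; the default
#' order attenuates a 50 Hz tone at fs = 128 to below 1% of its input RMS.
#'
#' @param rec an [recording()].
#' @param low_hz,high_hz band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth prototype order.
#' @return the filtered recording.
#' @export
bandpass <- function(rec, low_hz = 0.5, high_hz = 40, order = 4) {
  validate_recording(rec)
  nyq <- rec$fs / 2
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= nyq) {
    eegdenoise_abort("band edges must satisfy 0 < low < high < fs/2",
                     "eegdenoise_config_error")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])
  }
  out
}

#' Min-max normalize a recording to \[-1, 1\]
#'
#' Each channel is mapped by `x -> 2 (x - min) / (max - min) - 1` using its
#' own minimum and maximum over the whole recording, so every later segment is
#' bounded in \[-1, 1\]. Constant channels are mapped to all zeros and
#' flagged. The returned parameters invert the transform.
#'
#' @param rec an [recording()] with at least 2 samples per channel.
#' @return `list(rec =, params =)` where `params` is a data.frame with
#'   per-channel `min`, `max` and `constant` flag.
#' @export
minmax_normalize <- function(rec) {
  validate_recording(rec)
  if (ncol(rec$data) < 2L) {
    eegdenoise_abort("need at least 2 samples per channel",
                     "eegdenoise_config_error")
  }
  lo <- apply(rec$data, 1L, min)
  hi <- apply(rec$data, 1L, max)
  constant <- (hi - lo) < .Machine$double.eps
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- if (constant[ch]) {
      rep(0, ncol(rec$data))
    } else {
      2 * (rec$data[ch, ] - lo[ch]) / (hi[ch] - lo[ch]) - 1
    }
  }
  list(rec = out,
       params = data.frame(channel = rec$channel_names, min = lo, max = hi,
                           constant = constant, stringsAsFactors = FALSE))
}

#' @rdname minmax_normalize
#' @param params normalization parameters returned by `minmax_normalize`.
#' @return `denormalize`: the recording on its original scale (constant
#'   channels are restored to their constant value).
#' @export
denormalize <- function(rec, params) {
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- if (params$constant[ch]) {
      rep(params$min[ch], ncol(rec$data))
    } else {
      (rec$data[ch, ] + 1) / 2 * (params$max[ch] - params$min[ch]) + params$min[ch]
    }
  }
  out
}

#' Clip artifact epochs from an annotated recording
#'
#' One epoch per non-relax annotation, spanning the task block plus `pre_s`
#' seconds before and `post_s` seconds after (the standard epoch is
#' 11 + 2 + 2 = 15 s, i.e. F = T x fs = 1920 samples at 128 Hz). Epochs whose
#' flank runs past a recording boundary are truncated and flagged, or dropped
#' when `strict = TRUE`.
#'
#' @param rec an annotated [recording()].
#' @param pre_s,post_s flank durations in seconds.
#' @param strict drop boundary-truncated epochs instead of flagging them.
#' @return list of `eeg_epoch` objects: `data` (channels x F), `kind`, `T_s`,
#'   `F` (frame count), `subject_id`, `truncated` flag.
#' @export
clip_epochs <- function(rec, pre_s = 2, post_s = 2, strict = FALSE) {
  validate_recording(rec)
  ann <- rec$annotations
  tasks <- ann[ann$label != "relax", , drop = FALSE]
  if (!nrow(tasks)) {
    eegdenoise_abort("recording has no task annotations",
                     "eegdenoise_config_error")
  }
  if (any(tasks$duration_s <= 0)) {
    eegdenoise_abort("task blocks must have positive duration",
                     "eegdenoise_config_error")
  }
  n <- ncol(rec$data)
  epochs <- list()
  for (i in seq_len(nrow(tasks))) {
    want0 <- tasks$onset_s[i] - pre_s
    want1 <- tasks$onset_s[i] + tasks$duration_s[i] + post_s
    have0 <- max(want0, 0)
    have1 <- min(want1, n / rec$fs)
    truncated <- (have0 > want0 + 1e-9) || (have1 < want1 - 1e-9)
    if (truncated && strict) next
    i0 <- as.integer(round(have0 * rec$fs)) + 1L
    i1 <- as.integer(round(have1 * rec$fs))
    ep <- structure(
      list(data = rec$data[, i0:i1, drop = FALSE],
           kind = tasks$label[i], T_s = have1 - have0, F = i1 - i0 + 1L,
           fs = rec$fs, channel_names = rec$channel_names,
           subject_id = rec$subject_id, truncated = truncated),
      class = "eeg_epoch")
    epochs[[length(epochs) + 1L]] <- ep
  }
  epochs
}

#' Cut an epoch into non-overlapping fixed windows
#'
#' Each channel contributes `floor(F / (window_s * fs))` windows; the trailing
#' remainder is dropped. A 1920-sample (15-s) epoch at 128 Hz with 5-s windows
#' yields 3 windows per channel, i.e. 96 segments for 32 channels. Channel,
#' subject and artifact-kind metadata propagate to every segment.
#'
#' @param epoch an `eeg_epoch` from [clip_epochs()].
#' @param window_s window length in seconds.
#' @return a [segment_set()] (possibly empty when the epoch is shorter than
#'   one window).
#' @export
segment_epoch <- function(epoch, window_s = 5) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  wl <- as.integer(round(window_s * epoch$fs))
  nwin <- epoch$F %/% wl
  nch <- nrow(epoch$data)
  if (nwin == 0L) {
    return(segment_set(matrix(numeric(0), wl, 0L),
                       data.frame(subject_id = character(0),
                                  channel = character(0), kind = character(0),
                                  role = character(0)), epoch$fs))
  }
  x <- matrix(0, wl, nwin * nch)
  meta <- data.frame(subject_id = rep(epoch$subject_id, nwin * nch),
                     channel = rep(epoch$channel_names, each = nwin),
                     kind = rep(epoch$kind, nwin * nch),
                     role = NA_character_, stringsAsFactors = FALSE)
  k <- 1L
  for (ch in seq_len(nch)) {
    for (w in seq_len(nwin)) {
      x[, k] <- epoch$data[ch, ((w - 1L) * wl + 1L):(w * wl)]
      k <- k + 1L
    }
  }
  segment_set(x, meta, epoch$fs)
}

#' @rdname segment_epoch
#' @param epochs list of epochs.
#' @export
segment_epochs <- function(epochs, window_s = 5) {
  sets <- lapply(epochs, segment_epoch, window_s = window_s)
  do.call(bind_segments, sets)
}

#' Subject-held-out train/test split
#'
#' Deterministically assigns every segment of the held-out subject to the test
#' set and everyone else's to the training set, so no subject appears in both.
#' With 5 subjects and the four evaluation kinds (96 segments per subject and
#' kind) this gives the standard 80:20 split of 1536 training and 384 test
#' segments.
#'
#' @param segs a [segment_set()] from at least two subjects.
#' @param held_out subject id reserved for testing.
#' @return `list(train =, test =, held_out_subject =)`, both [segment_set()]s
#'   with the `role` metadata field set.
#' @export
split_by_subject <- function(segs, held_out) {
  subs <- unique(segs$meta$subject_id)
  if (!held_out %in% subs) {
    eegdenoise_abort("held-out subject not present", "eegdenoise_config_error")
  }
  if (length(subs) < 2L) {
    eegdenoise_abort("need at least two subjects to split",
                     "eegdenoise_config_error")
  }
  is_test <- segs$meta$subject_id == held_out
  train <- subset_segments(segs, !is_test)
  test <- subset_segments(segs, is_test)
  train$meta$role <- "train"
  test$meta$role <- "test"
  list(train = train, test = test, held_out_subject = held_out)
}

#' Run the standard preprocessing chain on one recording
#'
#' Filter, normalize, clip and segment, in that order, restricted to the
#' requested artifact kinds (the four evaluation kinds by default).
#'
#' @param rec an annotated [recording()].
#' @param low_hz,high_hz band-pass edges in Hz.
#' @param window_s segmentation window in seconds.
#' @param kinds artifact kinds to keep.
#' @param strict passed to [clip_epochs()].
#' @return `list(segments =, norm_params =)`.
#' @export
preprocess_recording <- function(rec, low_hz = 0.5, high_hz = 40,
                                 window_s = 5, kinds = evaluation_kinds(),
                                 strict = FALSE) {
  filt <- bandpass(rec, low_hz, high_hz)
  norm <- minmax_normalize(filt)
  epochs <- clip_epochs(norm$rec, strict = strict)
  epochs <- Filter(function(e) e$kind %in% kinds, epochs)
  segs <- segment_epochs(epochs, window_s = window_s)
  list(segments = segs, norm_params = norm$params)
}
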