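#' Construct a set of fixed-length EEG segments
#'
#' A segment is one single-channel, fixed-length, normalized window (5 s = 640
#' samples at 128 Hz in the standard setting); a `segment_set` stores many of
#' them column-wise together with their metadata. The same container carries
#' artifacted inputs, wavelet-cleaned training targets and denoiser outputs.
#'
#' @param x numeric matrix, `window_len` rows x one column per segment.
#' @param meta data.frame with one row per segment and columns `subject_id`,
#'   `channel`, `kind`, `role` (`"train"`, `"test"` or `NA`).
#' @param fs sampling rate in Hz the windows were cut at.
#' @return an object of class `segment_set`.
#' @export
segment_set <- function(x, meta, fs) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("subject_id", "channel", "kind", "role")
  for (col in setdiff(need, names(meta))) meta[[col]] <- NA_character_
  meta <- meta[need]
  if (nrow(meta) != ncol(x)) {
    eegdenoise_abort("meta rows must match segment columns",
                     "eegdenoise_format_error")
  }
  rownames(meta) <- NULL
  structure(list(x = x, meta = meta, fs = fs), class = "segment_set")
}

#' @rdname segment_set
#' @param segs a `segment_set`.
#' @export
n_segments <- function(segs) ncol(segs$x)

#' @rdname segment_set
#' @export
window_len <- function(segs) nrow(segs$x)

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %d samples @ %g Hz\n",
              n_segments(x), window_len(x), x$fs))
  if (n_segments(x)) {
    cat("  kinds:", paste(unique(x$meta$kind), collapse = ", "), "\n")
    cat("  subjects:", paste(unique(x$meta$subject_id), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Concatenate segment sets
#'
#' @param ... `segment_set` objects with equal window length and sampling rate.
#' @return a single `segment_set`.
#' @export
bind_segments <- function(...) {
  sets <- Filter(function(s) n_segments(s) > 0L, list(...))
  if (!length(sets)) {
    first <- list(...)[[1]]
    return(first)
  }
  wl <- vapply(sets, window_len, integer(1))
  if (length(unique(wl)) != 1L) {
    eegdenoise_abort("mixed segment lengths", "eegdenoise_format_error")
  }
  segment_set(do.call(cbind, lapply(sets, `[[`, "x")),
              do.call(rbind, lapply(sets, `[[`, "meta")),
              sets[[1]]$fs)
}

#' Subset a segment set
#'
#' @param segs a `segment_set`.
#' @param idx integer or logical index over segments.
#' @return the subsetted `segment_set`.
#' @export
subset_segments <- function(segs, idx) {
  segment_set(segs$x[, idx, drop = FALSE], segs$meta[idx, , drop = FALSE],
              segs$fs)
}
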