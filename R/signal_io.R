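#' Read a multichannel EEG recording
#'
#' Supports two formats. `"csv"`: one header row of channel names, one column
#' per channel, with the sampling rate, subject id and annotations carried in
#' a JSON sidecar `<path>.meta.json` (or `fs` passed explicitly). `"edf"`:
#' European Data Format, with annotations read from the EDF+ annotation
#' channel.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param fs sampling rate in Hz, required for CSV files without a sidecar.
#' @return an [recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    eegdenoise_abort(paste0("cannot read ", path), "eegdenoise_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  switch(format, csv = read_recording_csv(path, fs),
         edf = read_recording_edf(path))
}

#' Write a multichannel EEG recording
#'
#' CSV output is a lossless text round trip (header + one column per channel,
#' JSON sidecar with fs/subject/annotations). EDF output quantizes each
#' channel to 16 bits over its own physical min/max range and stores
#' annotations in an EDF+ annotation channel; the recording length must be a
#' whole number of seconds (1-s data records).
#'
#' @param rec an [recording()] object.
#' @param path destination path.
#' @param format `"auto"`, `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  validate_recording(rec)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  switch(format, csv = write_recording_csv(rec, path),
         edf = write_recording_edf(rec, path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

read_recording_csv <- function(path, fs = NULL) {
  probe <- paste(readLines(path, n = 5L, warn = FALSE), collapse = "")
  if (!nzchar(trimws(probe))) {
    eegdenoise_abort("empty CSV recording", "eegdenoise_format_error")
  }
  dt <- tryCatch(data.table::fread(path, header = TRUE),
                 error = function(e) {
                   eegdenoise_abort(paste0("unreadable CSV: ", conditionMessage(e)),
                                    "eegdenoise_io_error")
                 })
  if (nrow(dt) == 0L || ncol(dt) == 0L) {
    eegdenoise_abort("empty CSV recording", "eegdenoise_format_error")
  }
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (is.null(fs)) fs <- meta$fs
  if (is.null(fs)) {
    eegdenoise_abort("sampling rate missing: supply fs or a .meta.json sidecar",
                     "eegdenoise_config_error")
  }
  ann <- if (!is.null(meta$annotations) && length(meta$annotations)) {
    as.data.frame(meta$annotations, stringsAsFactors = FALSE)
  } else {
    empty_annotations()
  }
  data <- t(as.matrix(dt))
  dimnames(data) <- NULL
  recording(data, fs = fs, channel_names = names(dt),
            subject_id = if (is.null(meta$subject_id)) "unknown" else meta$subject_id,
            annotations = ann)
}

write_recording_csv <- function(rec, path) {
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$channel_names)
  data.table::fwrite(dt, path)
  jsonlite::write_json(
    list(fs = rec$fs, subject_id = rec$subject_id,
         annotations = rec$annotations),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- EDF (European Data Format, EDF+C with a TAL annotation channel) -------

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width = 8L) edf_pad(sprintf("%.6g", x), width)

write_recording_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    eegdenoise_abort("EDF writer requires an integer sampling rate",
                     "eegdenoise_config_error")
  }
  fs <- as.integer(round(fs))
  n_rec <- ncol(rec$data) / fs
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    eegdenoise_abort("EDF writer requires a whole number of seconds",
                     "eegdenoise_config_error")
  }
  n_rec <- as.integer(round(n_rec))
  nc <- nrow(rec$data)

  # annotation TALs; record 0 carries every annotation. TALs are separated by
  # NUL bytes, which R strings cannot hold, so records are built as raw vectors.
  tal_raw <- function(strs) {
    unlist(lapply(strs, function(s) c(charToRaw(s), as.raw(0L))))
  }
  anns <- rec$annotations
  rec0 <- tal_raw(c("+0\x14\x14",
                    if (nrow(anns)) {
                      sprintf("+%.6g\x15%.6g\x14%s\x14", anns$onset_s,
                              anns$duration_s, anns$label)
                    }))
  other <- lapply(seq_len(max(n_rec - 1L, 0L)),
                  function(r) tal_raw(sprintf("+%d\x14\x14", r)))
  ann_bytes <- max(length(rec0),
                   if (length(other)) max(lengths(other)) else 2L)
  ann_samples <- as.integer(ceiling(ann_bytes / 2))

  # per-channel physical range from data; parse back the printed header value
  # so writer and reader use the identical scaling
  pmin_s <- character(nc); pmax_s <- character(nc)
  for (ch in seq_len(nc)) {
    lo <- min(rec$data[ch, ]); hi <- max(rec$data[ch, ])
    if (hi - lo < 1e-12) hi <- lo + 1
    pmin_s[ch] <- sprintf("%.6g", lo)
    pmax_s[ch] <- sprintf("%.6g", hi)
  }
  pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)

  ns <- nc + 1L  # + annotation channel
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(edf_pad("0", 8))
  wr(edf_pad(rec$subject_id, 80))
  wr(edf_pad("eegdenoise recording", 80))
  wr(edf_pad("01.01.26", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256L * (1L + ns), 8))
  wr(edf_pad("EDF+C", 44))
  wr(edf_pad(n_rec, 8)); wr(edf_pad(1L, 8)); wr(edf_pad(ns, 4))
  wr(paste0(edf_pad(rec$channel_names, 16), collapse = ""))
  wr(edf_pad("EDF Annotations", 16))
  wr(strrep(" ", 80L * ns))                       # transducer
  wr(paste0(edf_pad(c(rep("uV", nc), ""), 8), collapse = ""))
  wr(paste0(edf_pad(c(pmin_s, "-1"), 8), collapse = ""))
  wr(paste0(edf_pad(c(pmax_s, "1"), 8), collapse = ""))
  wr(paste0(edf_pad(rep("-32768", ns), 8), collapse = ""))
  wr(paste0(edf_pad(rep("32767", ns), 8), collapse = ""))
  wr(strrep(" ", 80L * ns))                       # prefiltering
  wr(paste0(edf_pad(c(rep(fs, nc), ann_samples), 8), collapse = ""))
  wr(strrep(" ", 32L * ns))                       # reserved

  scale <- (pmax - pmin) / 65535
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nc)) {
      seg <- rec$data[ch, ((r - 1L) * fs + 1L):(r * fs)]
      dig <- as.integer(round((seg - pmin[ch]) / scale[ch])) - 32768L
      dig <- pmin(pmax(dig, -32768L), 32767L)
      writeBin(dig, con, size = 2L, endian = "little")
    }
    raw_tal <- if (r == 1L) rec0 else other[[r - 1L]]
    raw_tal <- c(raw_tal, raw(2L * ann_samples - length(raw_tal)))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    rawToChar(readBin(con, "raw", n))
  }
  num <- function(n) as.numeric(trimws(rd(n)))
  rd(8)                                  # version
  subject_id <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(num(8))
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  if (is.na(ns) || ns < 1L) {
    eegdenoise_abort("EDF file declares no signals", "eegdenoise_format_error")
  }
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  rd(80L * ns)
  rd(8L * ns)                            # physical dimension
  pmin <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  rd(80L * ns)
  spr <- vapply(seq_len(ns), function(i) as.integer(num(8)), integer(1))
  rd(32L * ns)

  is_ann <- labels == "EDF Annotations"
  data_ch <- which(!is_ann)
  if (!length(data_ch)) {
    eegdenoise_abort("EDF file has no data channels", "eegdenoise_format_error")
  }
  fs <- spr[data_ch[1]] / rec_dur
  data <- matrix(0, length(data_ch), n_rec * spr[data_ch[1]])
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_ann[s]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2L * spr[s]))
      } else {
        dig <- readBin(con, "integer", spr[s], size = 2L, endian = "little")
        ch <- match(s, data_ch)
        phys <- pmin[s] + (dig - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
        data[ch, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
      }
    }
  }
  recording(data, fs = fs, channel_names = labels[data_ch],
            subject_id = subject_id, annotations = parse_tals(ann_raw))
}

parse_tals <- function(ann_raw) {
  if (!length(ann_raw)) return(empty_annotations())
  # split the byte stream on NUL terminators, then decode each TAL
  is_nul <- ann_raw == as.raw(0L)
  starts <- c(1L, which(is_nul) + 1L)
  ends <- c(which(is_nul) - 1L, length(ann_raw))
  txt <- character(0)
  for (i in seq_along(starts)) {
    if (starts[i] <= ends[i]) {
      txt <- c(txt, rawToChar(ann_raw[starts[i]:ends[i]]))
    }
  }
  out <- list()
  for (tal in txt) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE, useBytes = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(parts[2])) next  # timestamp-only TAL
    od <- strsplit(parts[1], "\x15", fixed = TRUE, useBytes = TRUE)[[1]]
    out[[length(out) + 1L]] <- data.frame(
      label = parts[2], onset_s = as.numeric(od[1]),
      duration_s = if (length(od) > 1L) as.numeric(od[2]) else 0,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_annotations())
  ann <- do.call(rbind, out)
  ann[order(ann$onset_s), , drop = FALSE]
}

# ---- segment container -----------------------------------------------------

#' Save / load a segment container
#'
#' The container is a directory holding `segments.csv` (one row per segment,
#' full double precision) and `manifest.json` listing sampling rate, window
#' length and the per-segment metadata (subject, channel, artifact kind,
#' train/test role). The layout is stable and human-inspectable.
#'
#' @param segs a [segment_set()].
#' @param path directory to create/overwrite.
#' @return `save_segments`: `path`, invisibly. `load_segments`: a
#'   [segment_set()].
#' @export
save_segments <- function(segs, path) {
  if (!inherits(segs, "segment_set")) {
    eegdenoise_abort("save_segments expects a segment_set",
                     "eegdenoise_format_error")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(format = "eegdenoise-segments-v1", fs = segs$fs,
         window_len = window_len(segs), n_segments = n_segments(segs),
         meta = segs$meta),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  if (n_segments(segs) > 0L) {
    data.table::fwrite(data.table::as.data.table(t(segs$x)),
                       file.path(path, "segments.csv"), col.names = FALSE)
  } else {
    file.create(file.path(path, "segments.csv"))
  }
  invisible(path)
}

#' @rdname save_segments
#' @export
load_segments <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    eegdenoise_abort(paste0("no segment manifest under ", path),
                     "eegdenoise_io_error")
  }
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(man$format, "eegdenoise-segments-v1")) {
    eegdenoise_abort("unrecognized segment container format",
                     "eegdenoise_format_error")
  }
  meta <- if (length(man$meta)) {
    as.data.frame(man$meta, stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = character(0), channel = character(0),
               kind = character(0), role = character(0))
  }
  if (man$n_segments == 0L) {
    return(segment_set(matrix(numeric(0), man$window_len, 0L), meta, man$fs))
  }
  dt <- data.table::fread(file.path(path, "segments.csv"), header = FALSE)
  x <- t(as.matrix(dt))
  dimnames(x) <- NULL
  segment_set(x, meta, man$fs)
}
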