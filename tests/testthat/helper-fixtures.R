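# Shared fixtures, all generated in code under fixed seeds.

# small random recording for I/O round trips
tiny_recording <- function(n_ch = 4, dur_s = 6, fs = 128, seed = 101,
                           annotate = TRUE) {
  data <- withr::with_seed(seed, matrix(rnorm(n_ch * dur_s * fs, sd = 20),
                                        n_ch, dur_s * fs))
  ann <- if (annotate) {
    data.frame(label = c("relax", "eye_blink", "relax"),
               onset_s = c(0, 2, 4.5), duration_s = c(2, 2.5, 1.5),
               stringsAsFactors = FALSE)
  } else {
    empty_annotations()
  }
  recording(data, fs = fs, subject_id = "subT", annotations = ann)
}

# random segment set (window must be a multiple of 2^5 for the wavelet path)
tiny_segments <- function(n = 8, wl = 64, fs = 128, seed = 7,
                          kind = "eye_blink") {
  x <- withr::with_seed(seed, matrix(runif(wl * n, -1, 1), wl, n))
  segment_set(x, data.frame(subject_id = "subT", channel = paste0("ch", seq_len(n)),
                            kind = kind, role = NA_character_,
                            stringsAsFactors = FALSE), fs)
}

# one simulated multi-subject study at the standard scale; memoised because
# several test files reuse it
study_cache <- new.env(parent = emptyenv())
simulated_study <- function(n_subjects = 5, seed = 1) {
  key <- paste0("study_", n_subjects, "_", seed)
  if (!is.null(study_cache[[key]])) return(study_cache[[key]])
  prdm <- default_paradigm()
  segs <- lapply(seq_len(n_subjects), function(i) {
    ses <- make_session(prdm, seed = derive_seed(seed, 100 + i),
                        subject_id = paste0("sub", i))
    preprocess_recording(ses$contaminated)$segments
  })
  out <- do.call(bind_segments, segs)
  study_cache[[key]] <- out
  out
}

# band power helper used by spectral oracles
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- pmin(fs * (seq_len(n) - 1) / n, fs - fs * (seq_len(n) - 1) / n)
  sum(p[f >= lo & f < hi & seq_len(n) > 1])
}
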