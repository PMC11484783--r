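#' Standard EEG frequency bands
#'
#' Theta (4-8 Hz), Alpha (8-13 Hz), Beta (13-30 Hz) and Gamma (30-50 Hz).
#' Band membership is half-open (`lo <= f < hi`) so adjacent bands never
#' double-count a bin.
#'
#' @return data.frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("Theta", "Alpha", "Beta", "Gamma"),
             lo_hz = c(4, 8, 13, 30), hi_hz = c(8, 13, 30, 50),
             stringsAsFactors = FALSE)
}

check_pair <- function(a, b) {
  if (length(a) != length(b)) {
    eegdenoise_abort("input vectors must have equal length",
                     "eegdenoise_shape_error")
  }
  if (!length(a)) {
    eegdenoise_abort("input vectors must be non-empty",
                     "eegdenoise_shape_error")
  }
}

#' Normalized mean squared error
#'
#' `NMSE = MSE(org, rec) / ||org||_2^2` with `MSE = ||org - rec||_2^2 / N`.
#' Scale-invariant: rescaling both inputs by the same factor leaves it
#' unchanged. With `normalization = "variance"` the mean square is divided by
#' the original signal's variance instead of its squared norm.
#'
#' @param org_sig original signal vector (not all zero).
#' @param rec_sig reconstructed signal vector, same length.
#' @param normalization `"norm"` (default) or `"variance"`.
#' @return nonnegative scalar.
#' @export
nmse <- function(org_sig, rec_sig, normalization = c("norm", "variance")) {
  normalization <- match.arg(normalization)
  check_pair(org_sig, rec_sig)
  denom <- if (normalization == "norm") sum(org_sig^2) else var(org_sig)
  if (!is.finite(denom) || denom <= 0) {
    eegdenoise_abort("original signal has zero norm/variance: NMSE undefined",
                     "eegdenoise_undefined_error")
  }
  mean((org_sig - rec_sig)^2) / denom
}

#' Root mean squared error
#'
#' Square root of the mean squared elementwise difference; nonnegative and
#' symmetric in its arguments.
#'
#' @param data,estimate equal-length numeric vectors.
#' @return nonnegative scalar.
#' @export
rmse <- function(data, estimate) {
  check_pair(data, estimate)
  sqrt(mean((data - estimate)^2))
}

#' Pearson correlation coefficient between two signals
#'
#' Measures how well the variation of one signal linearly predicts the other;
#' in \[-1, 1\]. Both inputs must have nonzero variance.
#'
#' @param sig,sig_prime equal-length numeric vectors (length >= 2).
#' @return scalar correlation.
#' @export
cc <- function(sig, sig_prime) {
  check_pair(sig, sig_prime)
  if (length(sig) < 2L) {
    eegdenoise_abort("correlation needs at least 2 samples",
                     "eegdenoise_shape_error")
  }
  if (sd(sig) == 0 || sd(sig_prime) == 0) {
    eegdenoise_abort("zero-variance input: correlation undefined",
                     "eegdenoise_undefined_error")
  }
  stats::cor(sig, sig_prime)
}

#' In-band signal-to-noise ratio in dB
#'
#' Splits the magnitude-squared discrete Fourier coefficients of the whole
#' (rectangular-windowed) signal into in-band and out-of-band pools:
#' `SNR = 10 log10(P_signal / P_noise)` with
#' `P_noise = total power - P_signal`. The DC bin is excluded from both
#' pools, band membership is half-open (`lo <= f < hi`) over the folded
#' frequency axis, and by construction the two pools sum exactly to the total
#' AC power. A (near-)empty noise pool is capped at +300 dB and flagged via
#' the `"capped"` attribute.
#'
#' @param x numeric vector (length >= 2).
#' @param fs sampling rate in Hz.
#' @param band one row of [eeg_bands()] (or any list with `lo_hz`, `hi_hz`
#'   inside `(0, fs/2)`).
#' @return scalar dB, with attribute `capped = TRUE` when guarded.
#' @export
band_snr <- function(x, fs, band) {
  if (length(x) < 2L) {
    eegdenoise_abort("need at least 2 samples", "eegdenoise_shape_error")
  }
  lo <- band$lo_hz; hi <- band$hi_hz
  if (lo <= 0 || hi <= lo || hi > fs / 2) {
    eegdenoise_abort("band must lie within (0, fs/2]",
                     "eegdenoise_config_error")
  }
  n <- length(x)
  p <- Mod(fft(x))^2
  folded <- pmin(fs * (seq_len(n) - 1L) / n, fs - fs * (seq_len(n) - 1L) / n)
  ac <- seq_len(n)[-1L]                    # DC bin excluded from both pools
  in_band <- ac[folded[ac] >= lo & folded[ac] < hi]
  p_signal <- sum(p[in_band])
  p_total <- sum(p[ac])
  p_noise <- p_total - p_signal
  if (p_noise <= p_total * 1e-12) {
    return(structure(300, capped = TRUE))
  }
  if (p_signal == 0) {
    return(structure(-300, capped = TRUE))
  }
  10 * log10(p_signal / p_noise)
}

#' Signal-to-artifact ratio in dB
#'
#' `SAR = 10 log10( sd(A) / sd(A - A') )`: the ratio of the artifacted
#' signal's spread to the spread of the change the cleaner made. A null
#' cleaner (`A' = 0`) scores 0 dB; `A' == A` is capped at +300 dB and
#' flagged.
#'
#' @param a artifacted signal vector (nonzero spread).
#' @param a_prime cleaned signal vector, same length.
#' @return scalar dB, with attribute `capped = TRUE` when guarded.
#' @export
sar <- function(a, a_prime) {
  check_pair(a, a_prime)
  if (length(a) < 2L) {
    eegdenoise_abort("need at least 2 samples", "eegdenoise_shape_error")
  }
  s_a <- sd(a)
  if (s_a == 0) {
    eegdenoise_abort("sd(A) is zero: SAR undefined",
                     "eegdenoise_undefined_error")
  }
  s_r <- sd(a - a_prime)
  if (s_r <= s_a * 1e-15) {
    return(structure(300, capped = TRUE))
  }
  10 * log10(s_a / s_r)
}

#' Evaluate denoising methods against the original signals
#'
#' Computes, per electrode, NMSE/RMSE/CC/SAR of the wavelet-cleaned and
#' model-generated segments against the original (artifacted) segments —
#' per segment first, then averaged within electrode — plus per-band SNR of
#' the raw, wavelet and model signals averaged over all segments and
#' electrodes. A `Mean` row over electrodes is appended to every
#' per-electrode table. Guarded (capped) metric values are counted in
#' `flags`, never dropped.
#'
#' @param original [segment_set()] of artifacted segments.
#' @param wavelet [segment_set()] of wavelet-cleaned segments, aligned with
#'   `original`.
#' @param model [segment_set()] of model-denoised segments, aligned with
#'   `original`.
#' @param bands band table, defaults to [eeg_bands()].
#' @return a `metrics_report`: list of data.frames `nmse`, `rmse`, `cc`,
#'   `sar` (columns `channel`, `wavelet`, `model`), `snr` (columns `band`,
#'   `raw`, `wavelet`, `model`) and a `flags` count of capped cells.
#' @export
evaluate_denoising <- function(original, wavelet, model,
                               bands = eeg_bands()) {
  for (s in list(wavelet, model)) {
    if (n_segments(s) != n_segments(original) ||
        window_len(s) != window_len(original)) {
      eegdenoise_abort("segment sets must be aligned (same count and length)",
                       "eegdenoise_shape_error")
    }
  }
  fs <- original$fs
  channels <- unique(original$meta$channel)
  methods <- list(wavelet = wavelet, model = model)
  flags <- 0L

  per_metric <- list(nmse = nmse, rmse = rmse, cc = cc, sar = sar)
  tables <- lapply(per_metric, function(f) {
    tab <- data.frame(channel = channels, wavelet = NA_real_,
                      model = NA_real_, stringsAsFactors = FALSE)
    tab
  })
  for (ci in seq_along(channels)) {
    idx <- which(original$meta$channel == channels[ci])
    for (m in names(methods)) {
      for (nm in names(per_metric)) {
        f <- per_metric[[nm]]
        vals <- vapply(idx, function(j) {
          r <- f(original$x[, j], methods[[m]]$x[, j])
          if (isTRUE(attr(r, "capped"))) flags <<- flags + 1L
          as.numeric(r)
        }, numeric(1))
        tables[[nm]][ci, m] <- mean(vals)
      }
    }
  }

  add_mean_row <- function(tab) {
    rbind(tab, data.frame(channel = "Mean",
                          wavelet = mean(tab$wavelet), model = mean(tab$model),
                          stringsAsFactors = FALSE))
  }
  tables <- lapply(tables, add_mean_row)

  # band SNR: per segment on each signal variant, then averaged overall
  sets <- list(raw = original, wavelet = wavelet, model = model)
  snr_tab <- data.frame(band = bands$name, raw = NA_real_,
                        wavelet = NA_real_, model = NA_real_,
                        stringsAsFactors = FALSE)
  for (bi in seq_len(nrow(bands))) {
    band <- bands[bi, ]
    for (v in names(sets)) {
      vals <- vapply(seq_len(n_segments(original)), function(j) {
        s <- band_snr(sets[[v]]$x[, j], fs, band)
        if (isTRUE(attr(s, "capped"))) flags <<- flags + 1L
        as.numeric(s)
      }, numeric(1))
      snr_tab[bi, v] <- mean(vals)
    }
  }

  structure(list(nmse = tables$nmse, rmse = tables$rmse, cc = tables$cc,
                 sar = tables$sar, snr = snr_tab, flags = flags,
                 n_segments = n_segments(original), fs = fs),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d segments @ %g Hz", x$n_segments, x$fs))
  if (x$flags) cat(sprintf(" (%d capped cells)", x$flags))
  cat("\nMean rows:\n")
  for (nm in c("nmse", "rmse", "cc", "sar")) {
    m <- x[[nm]][x[[nm]]$channel == "Mean", ]
    cat(sprintf("  %-4s wavelet %8.4f  model %8.4f\n", toupper(nm),
                m$wavelet, m$model))
  }
  cat("Band SNR (dB):\n")
  print(x$snr, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as CSV tables
#'
#' One CSV per metric (`nmse.csv`, `rmse.csv`, `cc.csv`, `sar.csv`,
#' `snr.csv`) in the per-electrode rows + `Mean` row layout.
#'
#' @param report a `metrics_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("nmse", "rmse", "cc", "sar", "snr")) {
    data.table::fwrite(report[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Format a metrics report as Markdown tables
#'
#' @param report a `metrics_report`.
#' @return a character vector of Markdown lines.
#' @export
format_metrics_markdown <- function(report) {
  md_table <- function(tab, title) {
    hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    rows <- apply(tab, 1L, function(r) {
      paste0("| ", paste(vapply(r, function(v) {
        if (suppressWarnings(!is.na(as.numeric(v)))) {
          sprintf("%.4f", as.numeric(v))
        } else as.character(v)
      }, character(1)), collapse = " | "), " |")
    })
    c(paste0("### ", title), "", hdr, sep, rows, "")
  }
  c(md_table(report$nmse, "NMSE per electrode"),
    md_table(report$rmse, "RMSE per electrode"),
    md_table(report$cc, "CC per electrode"),
    md_table(report$sar, "SAR per electrode (dB)"),
    md_table(report$snr, "Band SNR (dB)"))
}
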