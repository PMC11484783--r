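#' Parameters for the wavelet reference cleaner
#'
#' The two-step cleaner that produces the training targets: a Savitzky-Golay
#' trend removal followed by multilevel wavelet decomposition with a single
#' threshold applied to every detail band. The threshold is
#' `threshold_factor` times the standard deviation of the third detail
#' coefficient band (hence `level >= 3`).
#'
#' @param family wavelet family: `"db4"` (default), `"db2"` or `"haar"`.
#' @param level decomposition depth (>= 3).
#' @param threshold_factor multiplier on sd of the level-3 detail band
#'   (default 0.8; 0 disables thresholding).
#' @param threshold_mode `"soft"` or `"hard"`.
#' @param golay_window odd smoother window length in samples (~1 s at 128 Hz
#'   by default, wide enough to track baseline drift without flattening
#'   delta-band content).
#' @param golay_order smoother polynomial order (< `golay_window`).
#' @return an object of class `wavelet_params`.
#' @export
wavelet_params <- function(family = "db4", level = 5, threshold_factor = 0.8,
                           threshold_mode = c("soft", "hard"),
                           golay_window = 129, golay_order = 3) {
  threshold_mode <- match.arg(threshold_mode)
  if (level < 3) {
    eegdenoise_abort("level must be >= 3 (threshold uses the third detail band)",
                     "eegdenoise_config_error")
  }
  if (golay_window %% 2 == 0 || golay_window <= golay_order) {
    eegdenoise_abort("golay_window must be odd and > golay_order",
                     "eegdenoise_config_error")
  }
  if (threshold_factor < 0) {
    eegdenoise_abort("threshold_factor must be >= 0",
                     "eegdenoise_config_error")
  }
  structure(list(family = family, level = as.integer(level),
                 threshold_factor = threshold_factor,
                 threshold_mode = threshold_mode,
                 golay_window = as.integer(golay_window),
                 golay_order = as.integer(golay_order)),
            class = "wavelet_params")
}

# orthonormal analysis low-pass filters (Daubechies)
wavelet_filter <- function(family) {
  switch(family,
         haar = , db1 = c(0.7071067811865476, 0.7071067811865476),
         db2 = c(-0.12940952255092145, 0.22414386804185735,
                 0.83651630373746899, 0.48296291314469025),
         db4 = c(-0.010597401784997278, 0.032883011666982945,
                 0.030841381835986965, -0.187034811718881140,
                 -0.027983769416983849, 0.630880767929590360,
                 0.714846570552541530, 0.230377813308855230),
         eegdenoise_abort(paste0("unknown wavelet family: ", family),
                          "eegdenoise_config_error"))
}

# circular cross-correlation of x with filter f via FFT
circ_corr <- function(x, f) {
  n <- length(x)
  fp <- c(f, rep(0, n - length(f)))
  Re(fft(fft(x) * Conj(fft(fp)), inverse = TRUE)) / n
}

# circular convolution of x with filter f via FFT
circ_conv <- function(x, f) {
  n <- length(x)
  fp <- c(f, rep(0, n - length(f)))
  Re(fft(fft(x) * fft(fp), inverse = TRUE)) / n
}

#' Periodized multilevel discrete wavelet transform
#'
#' Orthonormal DWT with circular (periodized) signal extension, so analysis
#' and synthesis are exact inverses to machine precision and coefficient
#' energy equals signal energy. The signal length must be divisible by
#' `2^level`.
#'
#' @param x numeric vector.
#' @param family wavelet family, see [wavelet_params()].
#' @param level decomposition depth.
#' @return list with `approx` (level-`level` approximation) and `detail`
#'   (list of detail bands, element `[[j]]` = level-j band), plus attributes
#'   for reconstruction.
#' @export
dwt_periodized <- function(x, family = "db4", level = 5) {
  h <- wavelet_filter(family)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)   # quadrature mirror high-pass
  n <- length(x)
  if (n < 2^level || n %% 2^level != 0) {
    eegdenoise_abort(
      sprintf("signal length %d must be a nonzero multiple of 2^level = %d",
              n, 2^level), "eegdenoise_config_error")
  }
  detail <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    lo <- circ_corr(a, h)
    hi <- circ_corr(a, g)
    idx <- seq(1L, length(a), by = 2L)
    detail[[j]] <- hi[idx]
    a <- lo[idx]
  }
  structure(list(approx = a, detail = detail),
            family = family, level = level, n = n, class = "eeg_dwt")
}

#' @rdname dwt_periodized
#' @param coeffs an `eeg_dwt` object.
#' @return `idwt_periodized`: the reconstructed numeric vector.
#' @export
idwt_periodized <- function(coeffs) {
  stopifnot(inherits(coeffs, "eeg_dwt"))
  h <- wavelet_filter(attr(coeffs, "family"))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  a <- coeffs$approx
  for (j in rev(seq_len(attr(coeffs, "level")))) {
    d <- coeffs$detail[[j]]
    m <- 2L * length(a)
    up_a <- numeric(m); up_a[seq(1L, m, by = 2L)] <- a
    up_d <- numeric(m); up_d[seq(1L, m, by = 2L)] <- d
    a <- circ_conv(up_a, h) + circ_conv(up_d, g)
  }
  a
}

#' Remove the slow trend with a Savitzky-Golay smoother
#'
#' Subtracts the Savitzky-Golay smoothed trend from the signal. Polynomials
#' up to the smoother order are reproduced exactly by the smoother, so a
#' linear ramp detrends to (numerically) zero.
#'
#' @param x numeric vector, longer than the smoother window.
#' @param params a [wavelet_params()].
#' @return the detrended vector, same length.
#' @export
detrend_golay <- function(x, params = wavelet_params()) {
  if (length(x) <= params$golay_window) {
    eegdenoise_abort("golay_window must be shorter than the signal",
                     "eegdenoise_config_error")
  }
  trend <- signal::sgolayfilt(x, p = params$golay_order,
                              n = params$golay_window)
  x - trend
}

#' Wavelet detail-coefficient threshold denoising
#'
#' Decomposes to `level`, computes a single threshold
#' `t = threshold_factor x sd(detail level 3)` and applies soft or hard
#' thresholding to every detail band; the approximation band is untouched.
#' The inverse transform returns a vector of the original length.
#'
#' @param x numeric vector (length a multiple of `2^level`).
#' @param params a [wavelet_params()].
#' @return the denoised vector.
#' @export
wavelet_denoise <- function(x, params = wavelet_params()) {
  cf <- dwt_periodized(x, params$family, params$level)
  t <- params$threshold_factor * sd_pop(cf$detail[[3L]])
  cf$detail <- lapply(cf$detail, threshold_coefs, t = t,
                      mode = params$threshold_mode)
  idwt_periodized(cf)
}

sd_pop <- function(w) sqrt(mean((w - mean(w))^2))

threshold_coefs <- function(w, t, mode) {
  if (mode == "soft") sign(w) * pmax(abs(w) - t, 0) else w * (abs(w) > t)
}

#' Produce a clean reference target from one artifacted segment
#'
#' The composed two-step cleaner: Savitzky-Golay trend removal, then wavelet
#' detail thresholding. The output is clipped to \[-1, 1\] (inputs are
#' normalized segments) and serves as the training target for the adversarial
#' denoiser.
#'
#' @param x numeric vector, one normalized segment.
#' @param params a [wavelet_params()].
#' @return the cleaned segment vector.
#' @export
clean_segment <- function(x, params = wavelet_params()) {
  y <- wavelet_denoise(detrend_golay(x, params), params)
  pmin(pmax(y, -1), 1)
}

#' @rdname clean_segment
#' @param segs a [segment_set()].
#' @return `clean_segments`: a [segment_set()] of reference targets with the
#'   input metadata preserved.
#' @export
clean_segments <- function(segs, params = wavelet_params()) {
  out <- segs
  for (j in seq_len(n_segments(segs))) {
    out$x[, j] <- clean_segment(segs$x[, j], params)
  }
  out
}

#' @rdname clean_segment
#' @param rec an [recording()]; each channel is cleaned independently. If the
#'   channel length is not a multiple of `2^level`, the largest conforming
#'   prefix is cleaned and the short tail is left unchanged.
#' @return `clean_recording`: the cleaned recording.
#' @export
clean_recording <- function(rec, params = wavelet_params()) {
  validate_recording(rec)
  out <- rec
  n <- ncol(rec$data)
  block <- 2^params$level
  m <- (n %/% block) * block
  for (ch in seq_len(nrow(rec$data))) {
    y <- wavelet_denoise(detrend_golay(rec$data[ch, seq_len(m)], params),
                         params)
    out$data[ch, seq_len(m)] <- y
  }
  out
}
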