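test_that("periodized DWT is orthonormal and perfectly invertible", {
  x <- withr::with_seed(1, rnorm(640))
  cf <- dwt_periodized(x, "db4", 5)
  xr <- idwt_periodized(cf)
  expect_lt(max(abs(xr - x)), 1e-9)
  # orthonormality: coefficient energy equals signal energy
  coef_energy <- sum(cf$approx^2) + sum(unlist(cf$detail)^2)
  expect_lt(abs(coef_energy - sum(x^2)) / sum(x^2), 1e-9)
  # lengths halve per level
  expect_equal(lengths(cf$detail), c(320L, 160L, 80L, 40L, 20L))
  expect_length(cf$approx, 20L)
})

test_that("DWT agrees with an explicit basis-matrix oracle", {
  # independent route: build the level-1 analysis operator as a dense matrix
  # of circularly shifted filters and compare
  h <- c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
         -0.187034811718881140, -0.027983769416983849, 0.630880767929590360,
         0.714846570552541530, 0.230377813308855230)
  g <- rev(h) * (-1)^(0:7)
  n <- 64
  y <- withr::with_seed(2, rnorm(n))
  A <- matrix(0, n / 2, n); D <- matrix(0, n / 2, n)
  for (k in 0:(n / 2 - 1)) {
    for (m in 0:7) {
      col <- ((2 * k + m) %% n) + 1
      A[k + 1, col] <- A[k + 1, col] + h[m + 1]
      D[k + 1, col] <- D[k + 1, col] + g[m + 1]
    }
  }
  cf <- dwt_periodized(y, "db4", 3)
  expect_lt(max(abs(cf$detail[[1]] - as.numeric(D %*% y))), 1e-12)
  # second level from the matrix route: analyze A %*% y again
  a1 <- as.numeric(A %*% y)
  A2 <- A[1:(n / 4), 1:(n / 2)] * 0; D2 <- A2
  for (k in 0:(n / 4 - 1)) {
    for (m in 0:7) {
      col <- ((2 * k + m) %% (n / 2)) + 1
      A2[k + 1, col] <- A2[k + 1, col] + h[m + 1]
      D2[k + 1, col] <- D2[k + 1, col] + g[m + 1]
    }
  }
  expect_lt(max(abs(cf$detail[[2]] - as.numeric(D2 %*% a1))), 1e-12)
})

test_that("thresholding behaves at both extremes", {
  x <- withr::with_seed(3, rnorm(640))
  # zero threshold, hard mode: perfect reconstruction
  y0 <- wavelet_denoise(x, wavelet_params(threshold_factor = 0,
                                          threshold_mode = "hard"))
  expect_lt(max(abs(y0 - x)), 1e-9)
  # zero input: zero threshold and zero output
  expect_equal(wavelet_denoise(rep(0, 640)), rep(0, 640))
  # huge threshold: everything but the approximation vanishes
  yinf <- wavelet_denoise(x, wavelet_params(threshold_factor = 1e6))
  cf <- dwt_periodized(x, "db4", 5)
  cf$detail <- lapply(cf$detail, function(w) w * 0)
  expect_lt(max(abs(yinf - idwt_periodized(cf))), 1e-9)
})

test_that("larger thresholds never increase the output's detail energy", {
  x <- withr::with_seed(4, cumsum(rnorm(640)) / 10)
  detail_energy <- function(v) {
    sum(unlist(dwt_periodized(v, "db4", 5)$detail)^2)
  }
  for (mode in c("soft", "hard")) {
    en <- vapply(c(0, 0.2, 0.5, 0.8, 1.5, 3), function(f) {
      detail_energy(wavelet_denoise(x, wavelet_params(threshold_factor = f,
                                                      threshold_mode = mode)))
    }, numeric(1))
    expect_true(all(diff(en) <= 1e-12))
  }
})

test_that("signals too short or misaligned for the transform are rejected", {
  expect_error(dwt_periodized(rnorm(16), "db4", 5),
               class = "eegdenoise_config_error")
  expect_error(dwt_periodized(rnorm(650), "db4", 5),
               class = "eegdenoise_config_error")
  expect_error(wavelet_params(level = 2), class = "eegdenoise_config_error")
  expect_error(wavelet_params(golay_window = 128),
               class = "eegdenoise_config_error")
})

test_that("Savitzky-Golay detrend reproduces polynomials and splits components", {
  ramp <- seq(0, 10, length.out = 640)
  out <- detrend_golay(ramp)
  # polynomial reproduction away from the window edges
  expect_lt(max(abs(out[130:510])), 1e-8 * diff(range(ramp)))
  expect_equal(detrend_golay(rep(0, 640)), rep(0, 640))
  # ramp + 10 Hz sine: the sine survives detrending
  tt <- (0:639) / 128
  sine <- sin(2 * pi * 10 * tt)
  expect_gt(cor(detrend_golay(ramp + sine), sine), 0.99)
  expect_error(detrend_golay(rnorm(100), wavelet_params(golay_window = 129)),
               class = "eegdenoise_config_error")
})

test_that("the composed cleaner substantially suppresses large blink spikes", {
  # fixture: one large positive spike on a clean background; the peak is
  # measured as the excursion from the segment median, since min-max
  # normalization offsets the baseline. The 1-s trend smoother and the
  # untouched approximation band leave part of the spike's slow core, so the
  # typical attenuation of the default cleaner is just under half; every
  # fixture must be clearly suppressed and the mean strongly so.
  ratio <- vapply(1:20, function(k) {
    bg <- make_background(5, 128, 1, seed = 200 + k)
    tpl <- artifact_template("eye_blink", amplitude_scale = 10,
                             rep_rate_hz = 0.2)
    con <- inject_artifact(bg, tpl, onset_s = 1.5, dur_s = 2, seed = 300 + k)
    x <- minmax_normalize(con)$rec$data[1, 1:640]
    y <- clean_segment(x)
    p <- which.max(abs(x - median(x)))
    abs(y[p] - median(y)) / abs(x[p] - median(x))
  }, numeric(1))
  expect_true(all(ratio < 0.65))
  expect_lt(mean(ratio), 0.6)
  # outputs stay normalized, length-preserving and metadata-preserving
  ses <- make_session(default_paradigm(n_channels = 4), seed = 55)
  blink <- preprocess_recording(ses$contaminated,
                                kinds = "eye_blink")$segments
  cleaned <- clean_segments(blink)
  expect_equal(dim(cleaned$x), dim(blink$x))
  expect_true(all(cleaned$x >= -1 & cleaned$x <= 1))
  expect_identical(cleaned$meta, blink$meta)
})

test_that("cleaning is contractive on simulated artifact segments", {
  ses <- make_session(default_paradigm(n_channels = 4), seed = 77)
  pp <- preprocess_recording(ses$contaminated)
  for (j in seq(1, n_segments(pp$segments), by = 12)) {
    x <- pp$segments$x[, j]
    y1 <- clean_segment(x)
    y2 <- clean_segment(y1)
    expect_lt(rmse(y2, y1), rmse(y1, x))
  }
})

test_that("a cleaned alpha tone remains alpha-dominant", {
  # the threshold is scaled by the level-3 detail band's own spread, so a
  # pure in-band tone is strongly shrunk; the honest invariant is that what
  # survives stays in the alpha band rather than leaking elsewhere
  tt <- (0:639) / 128
  x <- 0.5 * sin(2 * pi * 10 * tt)
  y <- clean_segment(x)
  alpha_frac <- band_power(y, 128, 8, 13) / band_power(y, 128, 0.5, 64)
  expect_gt(alpha_frac, 0.5)
  expect_gt(sd(y), 0)
})

test_that("recording-level cleaning matches per-channel cleaning", {
  rec <- make_background(5, 128, 3, seed = 12)
  nm <- minmax_normalize(rec)
  out <- clean_recording(nm$rec)
  for (ch in 1:3) {
    expect_equal(out$data[ch, ],
                 wavelet_denoise(detrend_golay(nm$rec$data[ch, ])),
                 tolerance = 1e-12)
  }
})
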