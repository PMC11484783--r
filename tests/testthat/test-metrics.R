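test_that("NMSE matches hand-computed values and is scale invariant", {
  expect_equal(nmse(c(1, 2, 3), c(1, 2, 3)), 0)
  # MSE = 1/3, squared norm = 14
  expect_equal(nmse(c(1, 2, 3), c(1, 2, 4)), (1 / 3) / 14, tolerance = 1e-12)
  for (seed in 1:5) {
    v <- withr::with_seed(seed, list(a = rnorm(50), b = rnorm(50),
                                     c = runif(1, 0.1, 10)))
    expect_equal(nmse(v$c * v$a, v$c * v$b), nmse(v$a, v$b),
                 tolerance = 1e-12)
    # brute-force agreement
    expect_equal(nmse(v$a, v$b),
                 (sum((v$a - v$b)^2) / 50) / sum(v$a^2), tolerance = 1e-9)
  }
  expect_error(nmse(rep(0, 5), rnorm(5)), class = "eegdenoise_undefined_error")
  expect_error(nmse(1:3, 1:4), class = "eegdenoise_shape_error")
  # prose variant: normalization by the variance
  a <- withr::with_seed(9, rnorm(64)); b <- withr::with_seed(10, rnorm(64))
  expect_equal(nmse(a, b, normalization = "variance"),
               mean((a - b)^2) / var(a), tolerance = 1e-12)
})

test_that("RMSE matches hand values, is symmetric and satisfies the triangle bound", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3), tolerance = 1e-12)
  for (seed in 1:5) {
    v <- withr::with_seed(seed, list(a = rnorm(40), b = rnorm(40),
                                     c = rnorm(40)))
    expect_equal(rmse(v$a, v$b), rmse(v$b, v$a), tolerance = 1e-12)
    expect_lte(rmse(v$a, v$c), rmse(v$a, v$b) + rmse(v$b, v$c) + 1e-12)
    expect_equal(rmse(v$a, v$b), sqrt(mean((v$a - v$b)^2)), tolerance = 1e-9)
  }
})

test_that("CC equals the covariance formula and catches degenerate input", {
  x <- withr::with_seed(1, rnorm(100))
  expect_equal(cc(x, x), 1)
  expect_equal(cc(x, -x), -1)
  for (seed in 1:5) {
    v <- withr::with_seed(seed, list(a = rnorm(30), b = rnorm(30)))
    brute <- sum((v$a - mean(v$a)) * (v$b - mean(v$b))) /
      (sqrt(sum((v$a - mean(v$a))^2)) * sqrt(sum((v$b - mean(v$b))^2)))
    expect_equal(cc(v$a, v$b), brute, tolerance = 1e-12)
    # affine invariance with positive slope
    expect_equal(cc(2.5 * v$a + 1, v$b), cc(v$a, v$b), tolerance = 1e-12)
  }
  # independent white noise decorrelates
  big <- withr::with_seed(42, list(a = rnorm(10000), b = rnorm(10000)))
  expect_lt(abs(cc(big$a, big$b)), 0.05)
  expect_error(cc(rep(1, 10), rnorm(10)), class = "eegdenoise_undefined_error")
})

test_that("band SNR resolves exact-bin tones and respects Parseval", {
  fs <- 128; n <- 640
  tt <- (seq_len(n) - 1) / fs
  # equal-amplitude tones on exact bins, one inside alpha and one outside
  x <- sin(2 * pi * 10 * tt) + sin(2 * pi * 45 * tt)
  alpha <- eeg_bands()[2, ]
  expect_equal(as.numeric(band_snr(x, fs, alpha)), 0, tolerance = 1e-9)
  # a pure in-band tone leaves no noise pool: capped and flagged
  pure <- band_snr(sin(2 * pi * 10 * tt), fs, alpha)
  expect_equal(as.numeric(pure), 300)
  expect_true(attr(pure, "capped"))
  expect_error(band_snr(x, fs, list(lo_hz = 30, hi_hz = 70)),
               class = "eegdenoise_config_error")
})

test_that("in-band plus out-of-band power equals total AC energy", {
  fs <- 128; n <- 641  # odd length: no exact Nyquist bin
  x <- withr::with_seed(8, rnorm(n))
  total_ac <- n * sum(x^2) - (sum(x))^2  # Parseval minus the DC bin
  cover <- list(list(lo_hz = 0.01, hi_hz = 16), list(lo_hz = 16, hi_hz = 32),
                list(lo_hz = 32, hi_hz = 64))
  p_signal <- vapply(cover, function(b) {
    r <- 10^(as.numeric(band_snr(x, fs, b)) / 10)
    total_ac * r / (1 + r)
  }, numeric(1))
  expect_equal(sum(p_signal), total_ac, tolerance = 1e-9)
})

test_that("SAR reproduces the scale oracles and guards degeneracy", {
  a <- withr::with_seed(5, rnorm(200))
  expect_equal(as.numeric(sar(a, rep(0, 200))), 0, tolerance = 1e-12)
  expect_equal(as.numeric(sar(a, a / 2)), 10 * log10(2), tolerance = 1e-12)
  capped <- sar(a, a)
  expect_equal(as.numeric(capped), 300)
  expect_true(attr(capped, "capped"))
  expect_error(sar(rep(3, 10), rnorm(10)), class = "eegdenoise_undefined_error")
})

test_that("the evaluation report aggregates electrodes exactly", {
  wl <- 64; n_ch <- 32; per_ch <- 2
  meta <- data.frame(subject_id = "sub5",
                     channel = rep(default_channel_names(n_ch), each = per_ch),
                     kind = "eye_blink", role = "test",
                     stringsAsFactors = FALSE)
  x <- withr::with_seed(11, matrix(rnorm(wl * n_ch * per_ch), wl))
  original <- segment_set(x, meta, 128)
  wavelet <- segment_set(x * 0.5 +
                           withr::with_seed(12, matrix(rnorm(length(x), sd = 0.1),
                                                       wl)), meta, 128)
  model <- original  # a perfect model reproduces the original exactly
  rep <- evaluate_denoising(original, wavelet, model)
  # 32 electrode rows plus one mean row
  expect_equal(nrow(rep$rmse), 33L)
  expect_identical(rep$rmse$channel[33], "Mean")
  # perfect model: NMSE 0, RMSE 0, CC 1 everywhere
  expect_equal(rep$nmse$model, rep(0, 33))
  expect_equal(rep$rmse$model, rep(0, 33))
  expect_equal(rep$cc$model, rep(1, 33), tolerance = 1e-12)
  # mean row is the arithmetic mean of the electrode rows
  for (nm in c("nmse", "rmse", "cc", "sar")) {
    expect_equal(rep[[nm]]$wavelet[33], mean(rep[[nm]]$wavelet[1:32]),
                 tolerance = 1e-12)
  }
  # model == original makes the model SAR undefined: capped and counted
  expect_true(all(rep$sar$model == 300))
  expect_gt(rep$flags, 0)
  expect_equal(nrow(rep$snr), 4L)
  # misaligned inputs are rejected
  expect_error(evaluate_denoising(original, wavelet,
                                  subset_segments(model, 1:3)),
               class = "eegdenoise_shape_error")
})

test_that("report export writes the five CSV tables and markdown", {
  segs <- tiny_segments(n = 4, wl = 64)
  segs$meta$channel <- rep(c("Fp1", "Fp2"), 2)
  rep <- evaluate_denoising(segs, segs, segs)  # degenerate but exportable
  dir <- file.path(withr::local_tempdir(), "metrics")
  write_metrics_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("nmse.csv", "rmse.csv",
                                               "cc.csv", "sar.csv",
                                               "snr.csv")))))
  md <- format_metrics_markdown(rep)
  expect_true(any(grepl("^### NMSE", md)))
  expect_true(any(grepl("^\\| Mean", md)))
})
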