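test_that("the full-width generator preserves the (640, 1) sequence shape", {
  gen <- build_generator(generator_spec(640, rep(64L, 4L)), seed = 1)
  X <- withr::with_seed(2, array(runif(2 * 640, -1, 1), c(2, 1, 640)))
  Y <- eegdenoise:::gen_forward(gen, X)$y
  expect_equal(dim(Y), c(2L, 1L, 640L))
  # tanh output bound
  expect_lt(max(abs(Y)), 1)
  # first recurrent layer parameter count: 4 ((1 + 64) 64 + 64)
  expect_equal(count_parameters(gen, layer = 1), 16896L)
  expect_equal(count_parameters(gen, layer = 1),
               4L * ((1L + 64L) * 64L + 64L))
})

test_that("the discriminator flattens 640 x 128 and scores in (0, 1)", {
  spec <- discriminator_spec(640, c(1024L, 512L, 256L, 128L))
  expect_equal(flatten_width(spec), 81920L)
  expect_equal(spec$units, c(1024L, 512L, 256L, 128L))
  disc <- build_discriminator(spec, seed = 1)
  expect_equal(nrow(disc$dense$W), 81920L)
  expect_equal(flatten_width(disc), 81920L)
  # forward pass at reduced widths: scalar output strictly inside (0, 1)
  small <- build_discriminator(discriminator_spec(64, c(8L, 4L)), seed = 3)
  X <- withr::with_seed(4, array(runif(5 * 64, -1, 1), c(5, 1, 64)))
  p <- eegdenoise:::disc_forward(small, X)$p
  expect_equal(dim(p), c(5L, 1L))
  expect_true(all(p > 0 & p < 1))
})

test_that("training is reproducible and decreases the identity-task loss", {
  ss <- tiny_segments(n = 32, wl = 64, seed = 7)
  cfg <- train_config(batch_size = 16, epochs = 5, seed = 3)
  run <- function() {
    train_denoiser(ss, ss, config = cfg,
                   gen_spec = generator_spec(64, c(8L, 8L)),
                   disc_spec = discriminator_spec(64, c(8L, 8L)))
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$generator, m2$generator)
  # identity task: the reconstruction loss falls every epoch
  expect_length(m1$history$gen_loss, 5L)
  expect_true(all(diff(m1$history$gen_loss) < 0))
  expect_true(all(is.finite(m1$history$disc_loss)))
})

test_that("a trained denoiser beats the raw input against wavelet targets", {
  tr <- make_session(default_paradigm(), seed = derive_seed(9, 1),
                     subject_id = "subA")
  te <- make_session(default_paradigm(), seed = derive_seed(9, 2),
                     subject_id = "subB")
  noisy_tr <- preprocess_recording(tr$contaminated,
                                   kinds = "eye_blink")$segments
  noisy_te <- preprocess_recording(te$contaminated,
                                   kinds = "eye_blink")$segments
  target_tr <- clean_segments(noisy_tr)
  target_te <- clean_segments(noisy_te)
  model <- train_denoiser(noisy_tr, target_tr,
                          config = train_config(batch_size = 32, epochs = 8,
                                                seed = 5),
                          gen_spec = generator_spec(640, c(16L, 16L)),
                          disc_spec = discriminator_spec(640, c(32L, 16L)))
  den <- denoise_segments(model, noisy_te)
  r_raw <- mean(vapply(seq_len(n_segments(noisy_te)), function(j) {
    rmse(target_te$x[, j], noisy_te$x[, j])
  }, numeric(1)))
  r_den <- mean(vapply(seq_len(n_segments(noisy_te)), function(j) {
    rmse(target_te$x[, j], den$x[, j])
  }, numeric(1)))
  expect_lt(r_den, r_raw)
})

test_that("denoising preserves counts, metadata, bounds and determinism", {
  ss <- tiny_segments(n = 17, wl = 64, seed = 19)
  model <- train_denoiser(ss, ss,
                          config = train_config(batch_size = 8, epochs = 2,
                                                seed = 2),
                          gen_spec = generator_spec(64, c(8L)),
                          disc_spec = discriminator_spec(64, c(8L)))
  out1 <- denoise_segments(model, ss)
  expect_equal(n_segments(out1), 17L)
  expect_identical(out1$meta, ss$meta)
  expect_true(all(abs(out1$x) < 1))
  expect_identical(denoise_segments(model, ss)$x, out1$x)
  # batched and one-at-a-time inference agree
  single <- denoise_segments(model, ss, batch_size = 1L)
  expect_lt(max(abs(single$x - out1$x)), 1e-6)
  # window mismatch is a shape error
  expect_error(denoise_segments(model, tiny_segments(n = 2, wl = 32)),
               class = "eegdenoise_shape_error")
})

test_that("unpaired training inputs are rejected", {
  a <- tiny_segments(n = 8, wl = 64)
  b <- tiny_segments(n = 6, wl = 64)
  expect_error(train_denoiser(a, b), class = "eegdenoise_config_error")
})

test_that("the discriminator stays frozen through a generator-only update", {
  ss <- tiny_segments(n = 8, wl = 64, seed = 23)
  gen <- build_generator(generator_spec(64, c(8L)), seed = 1)
  disc <- build_discriminator(discriminator_spec(64, c(8L)), seed = 2)
  before <- weight_checksum(disc)
  X <- array(0, c(8, 1, 64)); X[, 1, ] <- t(ss$x)
  gf <- eegdenoise:::gen_forward(gen, X, cache = TRUE)
  df <- eegdenoise:::disc_forward(disc, gf$y, cache = TRUE)
  # adversarial input-gradient only: no parameter gradients requested
  bw <- eegdenoise:::disc_backward(disc, df, (df$p - 1) / 8,
                                   want_params = FALSE)
  grads <- eegdenoise:::gen_backward(gen, gf, bw$dX)
  st <- eegdenoise:::adam_step(eegdenoise:::net_trainable(gen), grads,
                               eegdenoise:::adam_init(grads), train_config())
  gen2 <- eegdenoise:::net_set_trainable(gen, st$params)
  expect_identical(weight_checksum(disc), before)
  expect_false(identical(weight_checksum(gen2), weight_checksum(gen)))
})

test_that("a saved model reloads to bit-identical behaviour", {
  ss <- tiny_segments(n = 8, wl = 64, seed = 29)
  model <- train_denoiser(ss, ss,
                          config = train_config(batch_size = 4, epochs = 2,
                                                seed = 6),
                          gen_spec = generator_spec(64, c(8L)),
                          disc_spec = discriminator_spec(64, c(8L)))
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_denoiser(model, path)
  back <- load_denoiser(path)
  expect_identical(denoise_segments(back, ss)$x, denoise_segments(model, ss)$x)
  # config snapshot survives field by field
  expect_identical(back$config, model$config)
  expect_identical(back$history, model$history)
  # corrupted file fails to load
  bad <- file.path(withr::local_tempdir(), "bad.rds")
  writeLines("not an rds", bad)
  expect_error(load_denoiser(bad), class = "eegdenoise_load_error")
  # wrong payload fails the format check
  wrong <- file.path(withr::local_tempdir(), "wrong.rds")
  saveRDS(list(a = 1), wrong)
  expect_error(load_denoiser(wrong), class = "eegdenoise_load_error")
})

test_that("backpropagation matches central finite differences", {
  wl <- 8L; B <- 3L
  gen <- build_generator(generator_spec(wl, c(4L, 3L)), seed = 7)
  X <- withr::with_seed(42, array(rnorm(B * wl), c(B, 1, wl)))
  S <- withr::with_seed(43, array(rnorm(B * wl) * 0.5, c(B, 1, wl)))
  loss_fn <- function(net) mean((eegdenoise:::gen_forward(net, X)$y - S)^2)
  gf <- eegdenoise:::gen_forward(gen, X, cache = TRUE)
  gr <- eegdenoise:::gen_backward(gen, gf, 2 * (gf$y - S) / length(gf$y))
  eps <- 1e-6
  fd <- function(mutate) {
    gp <- mutate(gen, eps); gm <- mutate(gen, -eps)
    (loss_fn(gp) - loss_fn(gm)) / (2 * eps)
  }
  cases <- list(
    list(g = function() gr$layers[[1]]$W[5],
         m = function(g, e) { g$layers[[1]]$W[5] <- g$layers[[1]]$W[5] + e; g }),
    list(g = function() gr$layers[[2]]$U[7],
         m = function(g, e) { g$layers[[2]]$U[7] <- g$layers[[2]]$U[7] + e; g }),
    list(g = function() gr$layers[[1]]$b[2],
         m = function(g, e) { g$layers[[1]]$b[2] <- g$layers[[1]]$b[2] + e; g }),
    list(g = function() gr$layers[[1]]$alpha[1],
         m = function(g, e) { g$layers[[1]]$alpha[1] <- g$layers[[1]]$alpha[1] + e; g }),
    list(g = function() gr$dense$W[2],
         m = function(g, e) { g$dense$W[2] <- g$dense$W[2] + e; g }))
  for (cs in cases) {
    expect_equal(cs$g(), fd(cs$m), tolerance = 1e-5)
  }
  # discriminator: parameter gradient and input gradient
  disc <- build_discriminator(discriminator_spec(wl, c(4L, 3L)), seed = 9)
  bce1 <- function(net, Xa) {
    p <- pmin(pmax(eegdenoise:::disc_forward(net, Xa)$p, 1e-12), 1 - 1e-12)
    -mean(log(p))
  }
  df <- eegdenoise:::disc_forward(disc, X, cache = TRUE)
  bw <- eegdenoise:::disc_backward(disc, df, (df$p - 1) / B)
  d2 <- disc; d2$layers[[1]]$W[5] <- d2$layers[[1]]$W[5] + eps
  d3 <- disc; d3$layers[[1]]$W[5] <- d3$layers[[1]]$W[5] - eps
  expect_equal(bw$grads$layers[[1]]$W[5],
               (bce1(d2, X) - bce1(d3, X)) / (2 * eps), tolerance = 1e-5)
  Xp <- X; Xp[2, 1, 3] <- Xp[2, 1, 3] + eps
  Xm <- X; Xm[2, 1, 3] <- Xm[2, 1, 3] - eps
  expect_equal(bw$dX[2, 1, 3], (bce1(disc, Xp) - bce1(disc, Xm)) / (2 * eps),
               tolerance = 1e-5)
})
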