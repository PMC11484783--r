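#' Network architecture specifications
#'
#' The generator is a stack of LSTM layers returning full sequences, each
#' followed by a parametric rectifier (PReLU, learnable per-unit slope), and
#' a final per-timestep dense map to one unit with a tanh output, so it maps
#' a `(window_len, 1)` sequence to a `(window_len, 1)` sequence bounded in
#' (-1, 1). The discriminator is a stack of LSTM layers each followed by a
#' leaky rectifier (slope 0.2), a flatten layer of width
#' `window_len x last_units` and a single sigmoid unit. The default widths
#' are the full-scale architecture (four 64-unit generator layers;
#' 1024/512/256/128 discriminator layers).
#'
#' @param window_len sequence length in samples (640 for a 5-s segment at
#'   128 Hz).
#' @param units LSTM layer widths, input to output.
#' @param prelu_init initial PReLU slope.
#' @param leaky_alpha fixed negative slope of the discriminator rectifiers.
#' @return a spec object.
#' @export
generator_spec <- function(window_len = 640, units = rep(64L, 4L),
                           prelu_init = 0.25) {
  stopifnot(window_len >= 1, length(units) >= 1, all(units >= 1))
  structure(list(window_len = as.integer(window_len),
                 units = as.integer(units), prelu_init = prelu_init),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @export
discriminator_spec <- function(window_len = 640,
                               units = c(1024L, 512L, 256L, 128L),
                               leaky_alpha = 0.2) {
  stopifnot(window_len >= 1, length(units) >= 1, all(units >= 1))
  structure(list(window_len = as.integer(window_len),
                 units = as.integer(units), leaky_alpha = leaky_alpha),
            class = "discriminator_spec")
}

#' @rdname generator_spec
#' @param spec a `discriminator_spec` or built discriminator.
#' @return `flatten_width`: the width of the flatten layer,
#'   `window_len x last LSTM width`.
#' @export
flatten_width <- function(spec) {
  spec$window_len * tail(spec$units, 1L)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_lstm_layer <- function(n_in, n_units) {
  b <- rep(0, 4L * n_units)
  b[(n_units + 1L):(2L * n_units)] <- 1  # forget-gate bias at 1
  list(W = glorot(n_in, 4L * n_units), U = glorot(n_units, 4L * n_units),
       b = b)
}

#' Build the generator / discriminator networks
#'
#' Weight initialization (Glorot-uniform, forget-gate biases at 1) is fully
#' determined by `seed`.
#'
#' @param spec a [generator_spec()] / [discriminator_spec()].
#' @param seed integer seed.
#' @return a parameterized network object (`gan_generator` /
#'   `gan_discriminator`).
#' @export
build_generator <- function(spec = generator_spec(), seed = 1) {
  withr::with_seed(seed, {
    n_in <- 1L
    layers <- list()
    for (u in spec$units) {
      ly <- init_lstm_layer(n_in, u)
      ly$alpha <- rep(spec$prelu_init, u)
      layers[[length(layers) + 1L]] <- ly
      n_in <- u
    }
    dense <- list(W = glorot(n_in, 1L), b = 0)
    structure(list(window_len = spec$window_len, units = spec$units,
                   layers = layers, dense = dense),
              class = "gan_generator")
  })
}

#' @rdname build_generator
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1) {
  withr::with_seed(seed, {
    n_in <- 1L
    layers <- list()
    for (u in spec$units) {
      layers[[length(layers) + 1L]] <- init_lstm_layer(n_in, u)
      n_in <- u
    }
    dense <- list(W = glorot(spec$window_len * n_in, 1L), b = 0)
    structure(list(window_len = spec$window_len, units = spec$units,
                   leaky_alpha = spec$leaky_alpha, layers = layers,
                   dense = dense),
              class = "gan_discriminator")
  })
}

#' Parameter counts of a built network
#'
#' @param net a built network.
#' @param layer optional LSTM layer index; when given, only that layer's
#'   weights (input, recurrent and bias) are counted — for an LSTM this is
#'   the closed form `4 ((n_in + units) units + units)`.
#' @return integer parameter count.
#' @export
count_parameters <- function(net, layer = NULL) {
  if (!is.null(layer)) {
    ly <- net$layers[[layer]]
    return(length(ly$W) + length(ly$U) + length(ly$b))
  }
  tot <- sum(vapply(net$layers, function(ly) {
    length(ly$W) + length(ly$U) + length(ly$b) +
      if (is.null(ly$alpha)) 0L else length(ly$alpha)
  }, numeric(1)))
  as.integer(tot + length(net$dense$W) + length(net$dense$b))
}

# ---- forward / backward ----------------------------------------------------

# broadcast a per-unit vector over a (batch, units, time) array
unit_bcast <- function(v, B, T) array(rep(v, each = B), c(B, length(v), T))

sigmoid <- function(z) 1 / (1 + exp(-z))

gen_forward <- function(net, X, cache = FALSE) {
  B <- dim(X)[1]; T <- dim(X)[3]
  A <- X
  caches <- if (cache) vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    fw <- lstm_forward_cpp(A, ly$W, ly$U, ly$b)
    Hc <- fw$h
    alpha_arr <- unit_bcast(ly$alpha, B, T)
    A_out <- pmax(Hc, 0) + alpha_arr * pmin(Hc, 0)
    if (cache) caches[[li]] <- list(X_in = A, fw = fw)
    A <- A_out
  }
  H_last <- tail(net$units, 1L)
  Am <- matrix(aperm(A, c(1, 3, 2)), B * T, H_last)
  z <- Am %*% net$dense$W + net$dense$b
  Y <- array(0, c(B, 1L, T))
  Y[, 1L, ] <- matrix(tanh(z), B, T)
  out <- list(y = Y)
  if (cache) {
    out$caches <- caches
    out$Am <- Am
    out$A_last <- A
  }
  out
}

gen_backward <- function(net, fwd, dY) {
  B <- dim(dY)[1]; T <- dim(dY)[3]
  H_last <- tail(net$units, 1L)
  # through tanh + dense
  dz <- dY * (1 - fwd$y^2)
  dzm <- matrix(aperm(dz, c(1, 3, 2)), B * T, 1L)
  grads <- list(dense = list(W = crossprod(fwd$Am, dzm), b = sum(dzm)))
  dAm <- dzm %*% t(net$dense$W)
  dA <- aperm(array(dAm, c(B, T, H_last)), c(1, 3, 2))
  grads$layers <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    ly <- net$layers[[li]]
    ca <- fwd$caches[[li]]
    Hc <- ca$fw$h
    alpha_arr <- unit_bcast(ly$alpha, B, T)
    neg <- Hc < 0
    dH <- dA * ifelse(neg, alpha_arr, 1)
    dalpha <- apply(dA * pmin(Hc, 0), 2, sum)
    bw <- lstm_backward_cpp(dH, ca$X_in, ca$fw$h, ca$fw$c, ca$fw$i, ca$fw$f,
                            ca$fw$g, ca$fw$o, ly$W, ly$U)
    grads$layers[[li]] <- list(W = bw$dw, U = bw$du, b = as.numeric(bw$db),
                               alpha = dalpha)
    dA <- bw$dx
  }
  grads
}

disc_forward <- function(net, X, cache = FALSE) {
  B <- dim(X)[1]; T <- dim(X)[3]
  A <- X
  caches <- if (cache) vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    fw <- lstm_forward_cpp(A, ly$W, ly$U, ly$b)
    Hc <- fw$h
    A_out <- pmax(Hc, 0) + net$leaky_alpha * pmin(Hc, 0)
    if (cache) caches[[li]] <- list(X_in = A, fw = fw)
    A <- A_out
  }
  Fm <- matrix(A, B, tail(net$units, 1L) * T)
  logits <- Fm %*% net$dense$W + net$dense$b
  p <- sigmoid(logits)
  out <- list(p = p, logits = logits)
  if (cache) {
    out$caches <- caches
    out$Fm <- Fm
  }
  out
}

disc_backward <- function(net, fwd, dlogits, want_params = TRUE) {
  B <- nrow(dlogits); T <- net$window_len
  H_last <- tail(net$units, 1L)
  grads <- NULL
  if (want_params) {
    grads <- list(dense = list(W = crossprod(fwd$Fm, dlogits),
                               b = sum(dlogits)),
                  layers = vector("list", length(net$layers)))
  }
  dFm <- dlogits %*% t(net$dense$W)
  dA <- array(dFm, c(B, H_last, T))
  for (li in rev(seq_along(net$layers))) {
    ly <- net$layers[[li]]
    ca <- fwd$caches[[li]]
    Hc <- ca$fw$h
    dH <- dA * ifelse(Hc < 0, net$leaky_alpha, 1)
    bw <- lstm_backward_cpp(dH, ca$X_in, ca$fw$h, ca$fw$c, ca$fw$i, ca$fw$f,
                            ca$fw$g, ca$fw$o, ly$W, ly$U)
    if (want_params) {
      grads$layers[[li]] <- list(W = bw$dw, U = bw$du, b = as.numeric(bw$db))
    }
    dA <- bw$dx
  }
  list(dX = dA, grads = grads)
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(grads_template) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(grads_template), v = zero_like(grads_template), t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  upd <- function(p, g, m, v) {
    m2 <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v2 <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
    p2 <- p - cfg$learning_rate * (m2 / bc1) / (sqrt(v2 / bc2) + cfg$epsilon)
    list(p = p2, m = m2, v = v2)
  }
  # recurse by name where available: params and grads are built in different
  # top-level orders (layers/dense), so positional pairing would be wrong
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      out_p <- p; out_m <- m; out_v <- v
      for (k in keys) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      upd(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

net_trainable <- function(net) list(layers = net$layers, dense = net$dense)

net_set_trainable <- function(net, tr) {
  net$layers <- tr$layers
  net$dense <- tr$dense
  net
}

# grads arrive shaped like the trainable parameters already
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Training configuration for the adversarial denoiser
#'
#' Defaults follow the full-scale optimization setting: Adam with learning
#' rate 1e-3, beta1 0.9, beta2 0.999, epsilon 1e-8; batch size 128 over 500
#' epochs; generator loss weighted `w_mse x MSE + w_adv x BCE` with weights
#' (1.0, 5e-4).
#'
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param batch_size segments per update.
#' @param epochs training epochs.
#' @param w_mse,w_adv generator loss weights (reconstruction, adversarial).
#' @param seed master seed: weight initialization and batch shuffling derive
#'   from it, so training is reproducible run-to-run on one platform.
#' @param cadence `"batch"` (one discriminator step then one generator step
#'   per batch) or `"epoch"` (discriminator updated on the first batch of
#'   each epoch only).
#' @return a `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 128L, epochs = 500L,
                         w_mse = 1.0, w_adv = 5e-4, seed = 1L,
                         cadence = c("batch", "epoch")) {
  cadence <- match.arg(cadence)
  vals <- c(learning_rate, beta1, beta2, epsilon, batch_size, epochs, w_mse,
            w_adv)
  if (any(vals < 0) || learning_rate <= 0 || batch_size < 1 || epochs < 1) {
    eegdenoise_abort("training hyperparameters must be positive",
                     "eegdenoise_config_error")
  }
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), w_mse = w_mse, w_adv = w_adv,
                 seed = as.integer(seed), cadence = cadence),
            class = "train_config")
}

#' Model/training presets
#'
#' `full_preset()` is the full-scale architecture and optimization setting.
#' `desk_preset()` is a reduced configuration (2 x 16-unit generator, 32/16
#' discriminator, batch 32, 20 epochs) sized so a complete train/evaluate
#' cycle runs in minutes on one CPU core; it is the default for the pipeline
#' and the test suite.
#'
#' @param window_len segment length in samples.
#' @param seed master training seed.
#' @return list with `gen_spec`, `disc_spec`, `config`, `n_train_segments`
#'   (cap on training segments actually fed to the optimizer; `Inf` = all).
#' @export
full_preset <- function(window_len = 640, seed = 1) {
  list(name = "full",
       gen_spec = generator_spec(window_len, rep(64L, 4L)),
       disc_spec = discriminator_spec(window_len, c(1024L, 512L, 256L, 128L)),
       config = train_config(batch_size = 128L, epochs = 500L, seed = seed),
       n_train_segments = Inf)
}

#' @rdname full_preset
#' @export
desk_preset <- function(window_len = 640, seed = 1) {
  list(name = "desk",
       gen_spec = generator_spec(window_len, c(16L, 16L)),
       disc_spec = discriminator_spec(window_len, c(32L, 16L)),
       config = train_config(batch_size = 32L, epochs = 20L, seed = seed),
       n_train_segments = 384L)
}

#' Train the adversarial denoiser
#'
#' Alternating updates: the discriminator is trained with binary
#' cross-entropy to score wavelet-cleaned reference segments as real (label
#' 1) and generator outputs as fake (label 0); the generator — with the
#' discriminator frozen — minimizes
#' `w_mse x MSE(S', S) + w_adv x BCE(D(S'), 1)` where `S'` is its output and
#' `S` the index-aligned reference target. Training is deterministic under
#' `config$seed` on one platform.
#'
#' @param noisy [segment_set()] of artifacted input segments.
#' @param clean_ref [segment_set()] of index-aligned reference targets
#'   (typically [clean_segments()] of `noisy`).
#' @param config a [train_config()].
#' @param gen_spec,disc_spec architecture specs; default to the reduced desk
#'   sizes matched to `window_len`.
#' @param verbose print per-epoch losses.
#' @return a `trained_denoiser`: generator, discriminator, per-epoch loss
#'   history and a config snapshot.
#' @export
train_denoiser <- function(noisy, clean_ref, config = NULL,
                           gen_spec = NULL, disc_spec = NULL,
                           verbose = FALSE) {
  if (n_segments(noisy) != n_segments(clean_ref) ||
      window_len(noisy) != window_len(clean_ref)) {
    eegdenoise_abort("noisy and clean_ref must be index-aligned pairs",
                     "eegdenoise_config_error")
  }
  wl <- window_len(noisy)
  preset <- desk_preset(wl)
  if (is.null(config)) config <- preset$config
  if (is.null(gen_spec)) gen_spec <- preset$gen_spec
  if (is.null(disc_spec)) disc_spec <- preset$disc_spec
  if (gen_spec$window_len != wl || disc_spec$window_len != wl) {
    eegdenoise_abort("spec window_len must match the segments",
                     "eegdenoise_shape_error")
  }
  n <- n_segments(noisy)
  B <- min(config$batch_size, n)

  gen <- build_generator(gen_spec, seed = derive_seed(config$seed, 1))
  disc <- build_discriminator(disc_spec, seed = derive_seed(config$seed, 2))
  gen_state <- NULL; disc_state <- NULL
  history <- data.frame(epoch = seq_len(config$epochs), gen_loss = NA_real_,
                        disc_loss = NA_real_)
  last_disc_loss <- NA_real_

  withr::with_seed(derive_seed(config$seed, 3), {
    for (ep in seq_len(config$epochs)) {
      idx_all <- sample.int(n)
      n_batches <- max(1L, n %/% B)
      gl <- numeric(0); dl <- numeric(0)
      for (bi in seq_len(n_batches)) {
        idx <- idx_all[((bi - 1L) * B + 1L):(bi * B)]
        X <- array(0, c(B, 1L, wl)); S <- array(0, c(B, 1L, wl))
        X[, 1L, ] <- t(noisy$x[, idx, drop = FALSE])
        S[, 1L, ] <- t(clean_ref$x[, idx, drop = FALSE])

        gf <- gen_forward(gen, X, cache = TRUE)
        Sp <- gf$y

        update_disc <- config$cadence == "batch" || bi == 1L
        if (update_disc) {
          dfr <- disc_forward(disc, S, cache = TRUE)
          dff <- disc_forward(disc, Sp, cache = TRUE)
          d_loss <- 0.5 * (bce_loss(dfr$p, 1) + bce_loss(dff$p, 0))
          dlr <- (dfr$p - 1) / (2 * B)
          dlf <- dff$p / (2 * B)
          gr <- disc_backward(disc, dfr, dlr)$grads
          gf2 <- disc_backward(disc, dff, dlf)$grads
          g_sum <- add_grads(gr, gf2)
          if (is.null(disc_state)) disc_state <- adam_init(g_sum)
          st <- adam_step(net_trainable(disc), g_sum, disc_state, config)
          disc <- net_set_trainable(disc, st$params)
          disc_state <- st$state
          last_disc_loss <- d_loss
          dl <- c(dl, d_loss)
        }

        # generator update; discriminator weights are not touched here
        dfa <- disc_forward(disc, Sp, cache = TRUE)
        mse <- mean((Sp - S)^2)
        g_loss <- config$w_mse * mse + config$w_adv * bce_loss(dfa$p, 1)
        if (!is.finite(g_loss) || (update_disc && !is.finite(last_disc_loss))) {
          eegdenoise_abort(sprintf("training diverged (NaN loss) at epoch %d",
                                   ep), "eegdenoise_diverged_error")
        }
        dSp_mse <- config$w_mse * 2 * (Sp - S) / length(Sp)
        dSp_adv <- disc_backward(disc, dfa, (dfa$p - 1) / B,
                                 want_params = FALSE)$dX
        dSp <- dSp_mse + config$w_adv * dSp_adv
        g_grads <- gen_backward(gen, gf, dSp)
        if (is.null(gen_state)) gen_state <- adam_init(g_grads)
        st <- adam_step(net_trainable(gen), g_grads, gen_state, config)
        gen <- net_set_trainable(gen, st$params)
        gen_state <- st$state
        gl <- c(gl, g_loss)
      }
      history$gen_loss[ep] <- mean(gl)
      history$disc_loss[ep] <- if (length(dl)) mean(dl) else last_disc_loss
      if (verbose) {
        message(sprintf("epoch %3d  G %.6f  D %.6f", ep,
                        history$gen_loss[ep], history$disc_loss[ep]))
      }
    }
  })
  structure(list(generator = gen, discriminator = disc, history = history,
                 config = config, window_len = wl,
                 format = "eegdenoise-denoiser-v1"),
            class = "trained_denoiser")
}

add_grads <- function(a, b) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- add_grads(a[[k]], b[[k]])
    a
  } else {
    a + b
  }
}

#' Denoise segments with a trained generator
#'
#' Deterministic batched inference; one output segment per input with
#' metadata preserved and values in (-1, 1).
#'
#' @param model a `trained_denoiser` (or bare `gan_generator`).
#' @param segs a [segment_set()] whose window length matches the model.
#' @param batch_size inference batch size.
#' @return a [segment_set()] of denoised segments.
#' @export
denoise_segments <- function(model, segs, batch_size = 64L) {
  gen <- if (inherits(model, "trained_denoiser")) model$generator else model
  wl <- gen$window_len
  if (window_len(segs) != wl) {
    eegdenoise_abort(sprintf("segment length %d does not match model window %d",
                             window_len(segs), wl), "eegdenoise_shape_error")
  }
  n <- n_segments(segs)
  out <- segs
  if (n == 0L) return(out)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    X <- array(0, c(length(idx), 1L, wl))
    X[, 1L, ] <- t(segs$x[, idx, drop = FALSE])
    Y <- gen_forward(gen, X)$y
    out$x[, idx] <- t(matrix(Y[, 1L, ], length(idx), wl))
  }
  out
}

#' Save / load a trained denoiser
#'
#' The model (weights, loss history, config snapshot) is stored as a single
#' RDS file; a reloaded model reproduces identical denoising output.
#'
#' @param model a `trained_denoiser`.
#' @param path file path.
#' @return `save_denoiser`: `path` invisibly; `load_denoiser`: the model.
#' @export
save_denoiser <- function(model, path) {
  stopifnot(inherits(model, "trained_denoiser"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    eegdenoise_abort(paste0("cannot load denoiser: ", conditionMessage(e)),
                     "eegdenoise_load_error")
  })
  if (!inherits(model, "trained_denoiser") ||
      !identical(model$format, "eegdenoise-denoiser-v1")) {
    eegdenoise_abort("file is not a compatible trained denoiser",
                     "eegdenoise_load_error")
  }
  model
}

#' Checksum of a network's weights
#'
#' Used to assert the freeze contract: the discriminator's weights must be
#' unchanged across a generator-only update.
#'
#' @param net a built network.
#' @return numeric checksum.
#' @export
weight_checksum <- function(net) {
  sum(vapply(net$layers, function(ly) sum(ly$W) + sum(ly$U) + sum(ly$b),
             numeric(1))) + sum(net$dense$W) + net$dense$b
}
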