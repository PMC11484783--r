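#' Configuration for a full pipeline run
#'
#' Wires the stages simulate -> preprocess -> wavelet-clean -> train ->
#' denoise -> evaluate into one reproducible run. Every stochastic stage
#' derives its seed deterministically from the master seed.
#'
#' @param output_dir run directory (created if needed).
#' @param seed master seed.
#' @param preset `"desk"` (reduced sizes, minutes on one CPU) or `"full"`
#'   (full-scale architecture and 500 epochs).
#' @param n_subjects number of simulated subjects.
#' @param held_out subject id reserved for testing (defaults to the last).
#' @param kinds artifact kinds used for training/evaluation.
#' @param prdm session paradigm; defaults to [default_paradigm()].
#' @param templates artifact templates; defaults to [default_templates()].
#' @param wavelet reference-cleaner parameters.
#' @param low_hz,high_hz band-pass edges.
#' @param window_s segment window in seconds.
#' @param epochs optional override of the preset's training epochs.
#' @param n_train_segments optional override of the preset's cap on training
#'   segments fed to the optimizer.
#' @return a `run_config` object.
#' @export
run_config <- function(output_dir, seed = 1, preset = c("desk", "full"),
                       n_subjects = 5, held_out = NULL,
                       kinds = evaluation_kinds(), prdm = default_paradigm(),
                       templates = default_templates(),
                       wavelet = wavelet_params(), low_hz = 0.5,
                       high_hz = 40, window_s = 5, epochs = NULL,
                       n_train_segments = NULL) {
  preset <- match.arg(preset)
  wl <- as.integer(window_s * prdm$fs)
  pr <- if (preset == "desk") desk_preset(wl, seed) else full_preset(wl, seed)
  if (!is.null(epochs)) pr$config$epochs <- as.integer(epochs)
  if (!is.null(n_train_segments)) pr$n_train_segments <- n_train_segments
  pr$config$seed <- derive_seed(seed, 40)
  subjects <- paste0("sub", seq_len(n_subjects))
  if (is.null(held_out)) held_out <- tail(subjects, 1)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 preset = preset, model = pr, subjects = subjects,
                 held_out = held_out, kinds = kinds, prdm = prdm,
                 templates = templates, wavelet = wavelet, low_hz = low_hz,
                 high_hz = high_hz, window_s = window_s),
            class = "run_config")
}

stage_paths <- function(cfg) {
  out <- cfg$output_dir
  list(sessions = file.path(out, "sessions"),
       train_noisy = file.path(out, "segments", "train_noisy"),
       test_noisy = file.path(out, "segments", "test_noisy"),
       test_clean = file.path(out, "segments", "test_clean"),
       train_target = file.path(out, "segments", "train_target"),
       test_target = file.path(out, "segments", "test_target"),
       model = file.path(out, "model", "denoiser.rds"),
       history = file.path(out, "model", "history.csv"),
       denoised = file.path(out, "segments", "test_denoised"),
       metrics = file.path(out, "metrics"),
       manifest = file.path(out, "manifest.json"),
       log = file.path(out, "run.log"))
}

stage_done <- function(path) {
  if (grepl("\\.(rds|json|csv)$", path)) file.exists(path) else
    file.exists(file.path(path, "manifest.json"))
}

#' Run the artifact-removal pipeline
#'
#' Executes the stages in order, persisting each stage's outputs under the
#' run directory. A stage whose outputs already exist is skipped (cached), so
#' deleting e.g. the model file and re-running repeats training and the
#' stages after it while reusing the upstream segment containers. A
#' machine-readable manifest (config, seeds, package version) is written at
#' the end; it contains no timestamps, so reruns with the same master seed
#' reproduce it byte for byte.
#'
#' @param cfg a [run_config()].
#' @param stages subset of stages to run (in pipeline order).
#' @param force rerun stages even if their outputs exist.
#' @param verbose print per-stage progress.
#' @return the run directory, invisibly; metric CSVs live under
#'   `<output_dir>/metrics`.
#' @export
run_pipeline <- function(cfg,
                         stages = c("simulate", "preprocess", "wavelet",
                                    "train", "denoise", "evaluate"),
                         force = FALSE, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  p <- stage_paths(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS2"),
                    sprintf(...))
    cat(line, "\n", file = p$log, append = TRUE)
    if (verbose) message(line)
  }

  if ("simulate" %in% stages) {
    done <- file.exists(file.path(p$sessions,
                                  paste0(cfg$subjects, "_contaminated.csv")))
    if (force || !all(done)) {
      logf("stage simulate: %d subjects", length(cfg$subjects))
      dir.create(p$sessions, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(cfg$subjects)) {
        ses <- make_session(cfg$prdm, cfg$templates,
                            seed = derive_seed(cfg$seed, 100 + i),
                            subject_id = cfg$subjects[i])
        write_recording(ses$contaminated,
                        file.path(p$sessions,
                                  paste0(cfg$subjects[i], "_contaminated.csv")))
        write_recording(ses$clean,
                        file.path(p$sessions,
                                  paste0(cfg$subjects[i], "_clean.csv")))
      }
    } else logf("stage simulate: cached")
  }

  if ("preprocess" %in% stages) {
    if (force || !all(vapply(c(p$train_noisy, p$test_noisy, p$test_clean),
                             stage_done, logical(1)))) {
      logf("stage preprocess")
      noisy_all <- list(); clean_all <- list()
      for (s in cfg$subjects) {
        rec <- read_recording(file.path(p$sessions,
                                        paste0(s, "_contaminated.csv")))
        pp <- preprocess_recording(rec, cfg$low_hz, cfg$high_hz,
                                   cfg$window_s, cfg$kinds)
        noisy_all[[s]] <- pp$segments
        # ground-truth clean traces: same filtering, the contaminated
        # recording's normalization (so scales are comparable), same cuts
        cl <- read_recording(file.path(p$sessions, paste0(s, "_clean.csv")))
        cl <- bandpass(cl, cfg$low_hz, cfg$high_hz)
        cl$data <- sweep(sweep(cl$data, 1, (pp$norm_params$max +
                                              pp$norm_params$min) / 2),
                         1, (pp$norm_params$max - pp$norm_params$min) / 2, "/")
        cl$annotations <- rec$annotations
        eps <- clip_epochs(cl)
        eps <- Filter(function(e) e$kind %in% cfg$kinds, eps)
        clean_all[[s]] <- segment_epochs(eps, cfg$window_s)
      }
      noisy <- do.call(bind_segments, unname(noisy_all))
      clean <- do.call(bind_segments, unname(clean_all))
      split <- split_by_subject(noisy, cfg$held_out)
      save_segments(split$train, p$train_noisy)
      save_segments(split$test, p$test_noisy)
      clean_split <- split_by_subject(clean, cfg$held_out)
      save_segments(clean_split$test, p$test_clean)
    } else logf("stage preprocess: cached")
  }

  if ("wavelet" %in% stages) {
    if (force || !all(vapply(c(p$train_target, p$test_target), stage_done,
                             logical(1)))) {
      logf("stage wavelet-clean")
      save_segments(clean_segments(load_segments(p$train_noisy), cfg$wavelet),
                    p$train_target)
      save_segments(clean_segments(load_segments(p$test_noisy), cfg$wavelet),
                    p$test_target)
    } else logf("stage wavelet-clean: cached")
  }

  if ("train" %in% stages) {
    if (force || !stage_done(p$model)) {
      train_noisy <- load_segments(p$train_noisy)
      train_target <- load_segments(p$train_target)
      cap <- cfg$model$n_train_segments
      if (is.finite(cap) && cap < n_segments(train_noisy)) {
        # deterministic stratified subset across kinds
        keep <- withr::with_seed(derive_seed(cfg$seed, 41), {
          m <- train_noisy$meta
          unlist(lapply(split(seq_len(nrow(m)), m$kind), function(ix) {
            sample(ix, min(length(ix), ceiling(cap / length(unique(m$kind)))))
          }))
        })
        keep <- sort(keep[seq_len(min(cap, length(keep)))])
        train_noisy <- subset_segments(train_noisy, keep)
        train_target <- subset_segments(train_target, keep)
      }
      logf("stage train: %d pairs, %d epochs", n_segments(train_noisy),
           cfg$model$config$epochs)
      model <- train_denoiser(train_noisy, train_target,
                              config = cfg$model$config,
                              gen_spec = cfg$model$gen_spec,
                              disc_spec = cfg$model$disc_spec)
      dir.create(dirname(p$model), recursive = TRUE, showWarnings = FALSE)
      save_denoiser(model, p$model)
      data.table::fwrite(model$history, p$history)
    } else logf("stage train: cached")
  }

  if ("denoise" %in% stages) {
    if (force || !stage_done(p$denoised)) {
      logf("stage denoise")
      model <- load_denoiser(p$model)
      save_segments(denoise_segments(model, load_segments(p$test_noisy)),
                    p$denoised)
    } else logf("stage denoise: cached")
  }

  if ("evaluate" %in% stages) {
    logf("stage evaluate")
    report <- evaluate_denoising(load_segments(p$test_noisy),
                                 load_segments(p$test_target),
                                 load_segments(p$denoised))
    write_metrics_report(report, p$metrics)
    writeLines(format_metrics_markdown(report),
               file.path(p$metrics, "report.md"))
  }

  manifest <- list(
    package = "eegdenoise",
    version = as.character(utils::packageVersion("eegdenoise")),
    seed = cfg$seed, preset = cfg$preset, subjects = cfg$subjects,
    held_out = cfg$held_out, kinds = cfg$kinds,
    paradigm = cfg$prdm$blocks, fs = cfg$prdm$fs,
    n_channels = cfg$prdm$n_channels,
    band = c(cfg$low_hz, cfg$high_hz), window_s = cfg$window_s,
    wavelet = unclass(cfg$wavelet),
    train = unclass(cfg$model$config),
    gen_units = cfg$model$gen_spec$units,
    disc_units = cfg$model$disc_spec$units,
    n_train_segments = if (is.finite(cfg$model$n_train_segments))
      cfg$model$n_train_segments else "all")
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(cfg$output_dir)
}
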