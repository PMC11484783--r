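#' Recording-session paradigm
#'
#' A paradigm is an ordered list of blocks, each a `"relax"` pause or one of
#' the nine task labels, with a duration in seconds. The default paradigm
#' alternates a 2-s relax block with an 11-s task block for each of the nine
#' artifact kinds (evaluation kinds first), totalling 117 s; at 128 Hz that is
#' 14,976 samples per subject. A task's 2-s trailing flank is the next task's
#' leading relax block, so clipped 15-s epochs of consecutive tasks share
#' samples.
#'
#' @param blocks data.frame with columns `activity` (artifact kind or
#'   `"relax"`) and `duration_s`.
#' @param fs sampling rate in Hz (>= 100 so the gamma band up to 50 Hz exists).
#' @param n_channels number of channels.
#' @return an object of class `eeg_paradigm`.
#' @export
paradigm <- function(blocks, fs = 128, n_channels = 32) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  stopifnot(all(c("activity", "duration_s") %in% names(blocks)))
  known <- c(artifact_kinds(), "relax")
  if (!all(blocks$activity %in% known)) {
    eegdenoise_abort("unknown activity label in paradigm",
                     "eegdenoise_config_error")
  }
  if (any(blocks$duration_s <= 0)) {
    eegdenoise_abort("block durations must be positive",
                     "eegdenoise_config_error")
  }
  structure(list(blocks = blocks, fs = fs, n_channels = n_channels,
                 total_s = sum(blocks$duration_s)),
            class = "eeg_paradigm")
}

#' @rdname paradigm
#' @param relax_s,task_s block durations in seconds for the default layout.
#' @param kinds task order; defaults to all nine kinds, evaluation kinds first.
#' @export
default_paradigm <- function(fs = 128, n_channels = 32, relax_s = 2,
                             task_s = 11, kinds = artifact_kinds()) {
  blocks <- do.call(rbind, lapply(kinds, function(k) {
    data.frame(activity = c("relax", k), duration_s = c(relax_s, task_s),
               stringsAsFactors = FALSE)
  }))
  paradigm(blocks, fs = fs, n_channels = n_channels)
}

#' Artifact morphology template
#'
#' Parameterizes one artifact kind's injected waveform. Morphologies follow
#' the qualitative descriptions of the four evaluated kinds: eye blinks are
#' trains of high sudden positive spikes, eye movements are smoothed square
#' waves, chewing is a rhythmic amplitude-modulated theta-range burst and
#' teeth clenching is a high-frequency (20-45 Hz) EMG-like noise burst. The
#' non-evaluation kinds reuse the closest of these shapes.
#'
#' @param kind one of [artifact_kinds()].
#' @param amplitude_scale injected-component RMS relative to the background
#'   RMS over the contaminated span (> 0).
#' @param spike_width_s blink spike width in seconds.
#' @param rep_rate_hz repetition rate of spikes/bursts in Hz.
#' @param square_period_s period of the eye-movement square wave in seconds.
#' @param burst_band_hz two-vector, EMG noise band in Hz (below Nyquist).
#' @param carrier_hz chewing carrier frequency in Hz.
#' @return an object of class `artifact_template`.
#' @export
artifact_template <- function(kind, amplitude_scale = 5,
                              spike_width_s = 0.3, rep_rate_hz = 1,
                              square_period_s = 2,
                              burst_band_hz = c(20, 45), carrier_hz = 6) {
  if (!kind %in% artifact_kinds()) {
    eegdenoise_abort("unknown artifact kind", "eegdenoise_config_error")
  }
  if (amplitude_scale < 0) {
    eegdenoise_abort("amplitude_scale must be >= 0", "eegdenoise_config_error")
  }
  if (spike_width_s <= 0 || rep_rate_hz <= 0 || square_period_s <= 0 ||
      carrier_hz <= 0 || any(burst_band_hz <= 0) ||
      burst_band_hz[1] >= burst_band_hz[2]) {
    eegdenoise_abort("morphology parameters must be positive and ordered",
                     "eegdenoise_config_error")
  }
  structure(list(kind = kind, amplitude_scale = amplitude_scale,
                 spike_width_s = spike_width_s, rep_rate_hz = rep_rate_hz,
                 square_period_s = square_period_s,
                 burst_band_hz = burst_band_hz, carrier_hz = carrier_hz),
            class = "artifact_template")
}

#' @rdname artifact_template
#' @export
default_templates <- function() {
  tpl <- list(
    eye_blink     = artifact_template("eye_blink", amplitude_scale = 8,
                                      spike_width_s = 0.3, rep_rate_hz = 1),
    eye_movement  = artifact_template("eye_movement", amplitude_scale = 5,
                                      square_period_s = 2),
    chewing       = artifact_template("chewing", amplitude_scale = 3,
                                      rep_rate_hz = 1.5, carrier_hz = 6),
    clench_teeth  = artifact_template("clench_teeth", amplitude_scale = 6,
                                      burst_band_hz = c(20, 45)))
  # the five remaining kinds reuse the nearest morphology
  tpl$swallowing        <- artifact_template("swallowing", 3, rep_rate_hz = 0.5)
  tpl$tongue_movement   <- artifact_template("tongue_movement", 3,
                                             square_period_s = 2.5)
  tpl$jaw_movement      <- artifact_template("jaw_movement", 4,
                                             burst_band_hz = c(15, 40))
  tpl$head_movement     <- artifact_template("head_movement", 4,
                                             square_period_s = 3)
  tpl$shoulder_movement <- artifact_template("shoulder_movement", 3,
                                             square_period_s = 3)
  tpl
}

#' Generate a clean synthetic EEG background
#'
#' Per channel: 1/f-weighted Gaussian noise (spectral power slope `-slope`
#' over 1-40 Hz) plus an alpha-band oscillation with a random phase. Channels
#' are zero-mean (within 1e-6 x RMS) and deterministic under `seed`.
#'
#' @param dur_s duration in seconds (> 0).
#' @param fs sampling rate in Hz (>= 100; the 30-50 Hz gamma band must exist).
#' @param n_channels number of channels.
#' @param seed integer seed.
#' @param slope spectral power slope magnitude of the noise floor.
#' @param alpha_hz alpha oscillation frequency in Hz.
#' @param alpha_amp alpha amplitude relative to unit noise RMS.
#' @param base_rms overall per-channel RMS in microvolts.
#' @param subject_id label stored in the recording.
#' @return an [recording()] with no annotations.
#' @export
make_background <- function(dur_s, fs = 128, n_channels = 32, seed = 1,
                            slope = 1, alpha_hz = 10, alpha_amp = 1,
                            base_rms = 10, subject_id = "sub1") {
  if (dur_s <= 0) {
    eegdenoise_abort("duration must be positive", "eegdenoise_config_error")
  }
  if (fs < 100) {
    eegdenoise_abort("fs must be >= 100 Hz so the gamma band (30-50 Hz) is representable",
                     "eegdenoise_config_error")
  }
  n <- as.integer(round(dur_s * fs))
  tt <- (seq_len(n) - 1L) / fs
  freqs <- fs * (seq_len(n) - 1L) / n
  folded <- pmin(freqs, fs - freqs)
  w <- ifelse(folded > 0, folded^(-slope / 2), 0)
  data <- withr::with_seed(seed, {
    m <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      spec <- fft(rnorm(n)) * w
      noise <- Re(fft(spec, inverse = TRUE)) / n
      noise <- noise / sqrt(mean(noise^2))
      phase <- runif(1, 0, 2 * pi)
      x <- noise + alpha_amp * sin(2 * pi * alpha_hz * tt + phase)
      x <- x / sqrt(mean(x^2)) * base_rms
      m[ch, ] <- x - mean(x)
    }
    m
  })
  recording(data, fs = fs, subject_id = subject_id)
}

# unit-RMS artifact waveform over n samples for one template (seeded)
artifact_waveform <- function(template, n, fs, seed) {
  tt <- (seq_len(n) - 1L) / fs
  nyq <- fs / 2
  w <- withr::with_seed(seed, {
    switch(
      template$kind,
      eye_blink = , swallowing = {
        # train of positive biexponential spikes with jittered onsets
        tau_r <- template$spike_width_s / 6
        tau_d <- template$spike_width_s / 2.5
        period <- 1 / template$rep_rate_hz
        onsets <- seq(0.2, max(n / fs - template$spike_width_s, 0.2), by = period)
        onsets <- onsets + runif(length(onsets), -0.1, 0.1) * period
        x <- numeric(n)
        for (o in onsets) {
          t_rel <- tt - o
          act <- t_rel >= 0
          x[act] <- x[act] + (exp(-t_rel[act] / tau_d) - exp(-t_rel[act] / tau_r))
        }
        x
      },
      eye_movement = , tongue_movement = , head_movement = ,
      shoulder_movement = {
        # smoothed square wave ("square waves")
        f0 <- 1 / template$square_period_s
        phase <- runif(1, 0, 2 * pi)
        tanh(6 * sin(2 * pi * f0 * tt + phase))
      },
      chewing = {
        # rhythmic amplitude-modulated theta-range bursts
        phase <- runif(1, 0, 2 * pi)
        carrier <- sin(2 * pi * template$carrier_hz * tt + phase) +
          0.3 * bandlimited_noise(n, fs, c(4, 8))
        env <- pmax(sin(2 * pi * template$rep_rate_hz * tt), 0)^2
        carrier * env
      },
      jaw_movement = , clench_teeth = {
        # high-frequency EMG-like noise bursts ("high-amplitude spikes")
        band <- pmin(template$burst_band_hz, nyq * 0.98)
        env <- pmax(sin(2 * pi * max(template$rep_rate_hz, 0.75) * tt), 0)
        bandlimited_noise(n, fs, band) * (0.2 + env)
      })
  })
  rms <- sqrt(mean(w^2))
  if (rms > 0) w / rms else w
}

# white noise restricted to [lo, hi] Hz by FFT masking
bandlimited_noise <- function(n, fs, band) {
  spec <- fft(rnorm(n))
  freqs <- fs * (seq_len(n) - 1L) / n
  folded <- pmin(freqs, fs - freqs)
  spec[folded < band[1] | folded > band[2]] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  if (sd(x) > 0) x / sd(x) else x
}

#' Inject an artifact into a recording
#'
#' Adds the template's waveform over `[onset_s, onset_s + dur_s]`, scaled so
#' the injected component's RMS is `amplitude_scale` times the recording's
#' background RMS, with a frontal-weighted spatial profile across channels.
#' The injected component is accumulated in the returned recording's
#' `artifact` field, so `contaminated == clean + artifact` exactly and the
#' ground truth stays retrievable. The signal outside the span is unchanged.
#'
#' @param rec an [recording()].
#' @param template an [artifact_template()].
#' @param onset_s,dur_s span of the injection in seconds.
#' @param seed integer seed for the waveform.
#' @param spatial_profile per-channel gains; default decays linearly from 1
#'   (frontal) to 0.3 (posterior).
#' @return the contaminated recording copy.
#' @export
inject_artifact <- function(rec, template, onset_s, dur_s, seed = 1,
                            spatial_profile = NULL) {
  validate_recording(rec)
  n <- ncol(rec$data)
  i0 <- as.integer(round(onset_s * rec$fs)) + 1L
  i1 <- as.integer(round((onset_s + dur_s) * rec$fs))
  if (i0 < 1L || i1 > n || i1 < i0) {
    eegdenoise_abort("artifact span outside the recording",
                     "eegdenoise_range_error")
  }
  nch <- nrow(rec$data)
  if (is.null(spatial_profile)) {
    spatial_profile <- seq(1, 0.3, length.out = nch)
  }
  span <- i0:i1
  base_rms <- sqrt(mean(rec$data^2))
  wave <- artifact_waveform(template, length(span), rec$fs, seed)
  comp <- outer(spatial_profile, wave) * template$amplitude_scale * base_rms
  out <- rec
  if (is.null(out$artifact)) out$artifact <- matrix(0, nch, n)
  out$data[, span] <- out$data[, span] + comp
  out$artifact[, span] <- out$artifact[, span] + comp
  out
}

#' Simulate a full recording session
#'
#' Walks the paradigm, generates one shared clean background, annotates every
#' block and contaminates each task block with its template. Relax blocks are
#' untouched. The clean and contaminated recordings differ exactly by the
#' stored `artifact` component.
#'
#' @param prdm an [paradigm()].
#' @param templates named list of [artifact_template()], one per task kind in
#'   the paradigm.
#' @param seed master seed; background and per-block waveforms derive from it.
#' @param subject_id subject label.
#' @param spontaneous_blinks if `TRUE`, a weak eye-blink train is also
#'   superimposed on non-blink task blocks (subjects blink involuntarily);
#'   off by default so unit tests see one morphology per block.
#' @return `list(contaminated =, clean =)`, both [recording()]s with
#'   identical annotations.
#' @export
make_session <- function(prdm, templates = default_templates(), seed = 1,
                         subject_id = "sub1", spontaneous_blinks = FALSE) {
  stopifnot(inherits(prdm, "eeg_paradigm"))
  task_kinds <- setdiff(unique(prdm$blocks$activity), "relax")
  missing <- setdiff(task_kinds, names(templates))
  if (length(missing)) {
    eegdenoise_abort(paste0("no template for: ", paste(missing, collapse = ", ")),
                     "eegdenoise_config_error")
  }
  clean <- make_background(prdm$total_s, prdm$fs, prdm$n_channels,
                           seed = derive_seed(seed, 0), subject_id = subject_id)
  onsets <- cumsum(c(0, head(prdm$blocks$duration_s, -1)))
  clean$annotations <- data.frame(label = prdm$blocks$activity,
                                  onset_s = onsets,
                                  duration_s = prdm$blocks$duration_s,
                                  stringsAsFactors = FALSE)
  contaminated <- clean
  for (b in seq_len(nrow(prdm$blocks))) {
    act <- prdm$blocks$activity[b]
    if (act == "relax") next
    contaminated <- inject_artifact(contaminated, templates[[act]],
                                    onsets[b], prdm$blocks$duration_s[b],
                                    seed = derive_seed(seed, b))
    if (spontaneous_blinks && act != "eye_blink" &&
        !is.null(templates$eye_blink)) {
      weak <- templates$eye_blink
      weak$amplitude_scale <- weak$amplitude_scale * 0.25
      contaminated <- inject_artifact(contaminated, weak, onsets[b],
                                      prdm$blocks$duration_s[b],
                                      seed = derive_seed(seed, 1000L + b))
    }
  }
  list(contaminated = contaminated, clean = clean)
}
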