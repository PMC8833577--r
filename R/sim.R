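#' Simulation configuration for synthetic iEEG cohorts
#'
#' Builds the configuration object consumed by [generate_background()],
#' [synthesize_event_waveform()], [simulate_event_window()] and
#' [generate_cohort()].  Defaults describe an interictal subdural recording:
#' 2000 Hz sampling, 1/f Gaussian background, and sparse HFO/artefact events
#' whose per-channel Poisson rates sum to roughly 0.6 events/min/channel.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param n_patients Number of patients in the cohort.
#' @param channels_per_patient Electrode contacts per patient.
#' @param recording_minutes Minutes of recording per patient.
#' @param seizure_free_fraction Fraction of patients seizure-free at 24-month
#'   follow-up.
#' @param event_rates Named list of events/min/channel for the five true event
#'   classes (`ripple`, `fast_ripple`, `hfo_with_spike`, `ringing_artefact`,
#'   `noise_artefact`).
#' @param background_params List with `alpha` (1/f spectral exponent) and
#'   `scale` (background RMS in signal units, nominally microvolts).
#' @param amplitude_factor Peak amplitude of injected oscillations relative to
#'   the 80-500 Hz band-passed background RMS.
#' @param ehfo_morphology List describing the epileptogenic signature:
#'   `onset_boost` (multiplicative broadband power boost within +/-45 ms of
#'   event centre), `lowfreq_amplitude_factor` and `lowfreq_envelope_ms`
#'   (10-59 Hz component spanning the analysis window), `spike_amplitude_factor`
#'   and `spike_width_ms` (co-occurring monophasic spike transient).
#' @param artefact_params List with `ring_decay_cycles` (e-folding of the
#'   ringing transient, in oscillation cycles) and `transient_width_ms` (sharp
#'   transient width).
#' @param label_noise Fraction of resected-channel HFO events (in seizure-free
#'   patients) that carry non-epileptogenic morphology.
#' @param resected_fraction,soz_fraction Fraction of channels resected /
#'   flagged as seizure-onset zone per patient.
#' @param seed Integer seed; identical seed and config reproduce the cohort
#'   bit for bit.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 2000,
                       n_patients = 19,
                       channels_per_patient = 96,
                       recording_minutes = 10,
                       seizure_free_fraction = 9 / 14,
                       event_rates = list(ripple = 0.2, fast_ripple = 0.1,
                                          hfo_with_spike = 0.2,
                                          ringing_artefact = 0.08,
                                          noise_artefact = 0.05),
                       background_params = list(alpha = 1.0, scale = 10),
                       amplitude_factor = 10,
                       ehfo_morphology = list(onset_boost = 2,
                                              lowfreq_amplitude_factor = 1.2,
                                              lowfreq_envelope_ms = 900,
                                              spike_amplitude_factor = 3,
                                              spike_width_ms = 60),
                       artefact_params = list(ring_decay_cycles = 1.5,
                                              transient_width_ms = 3),
                       label_noise = 0.2,
                       resected_fraction = 0.3,
                       soz_fraction = 0.12,
                       seed = 1L) {
  assert_that(sampling_rate > 2 * 500,
              "sampling_rate must exceed twice the highest synthesized frequency (500 Hz)")
  assert_that(seizure_free_fraction >= 0 && seizure_free_fraction <= 1,
              "seizure_free_fraction must lie in [0, 1]")
  assert_that(all(unlist(event_rates) >= 0), "event rates must be non-negative")
  assert_that(label_noise >= 0 && label_noise <= 1, "label_noise must lie in [0, 1]")
  assert_that(is_count(n_patients) && is_count(channels_per_patient),
              "n_patients and channels_per_patient must be positive integers")
  structure(list(sampling_rate = sampling_rate, n_patients = as.integer(n_patients),
                 channels_per_patient = as.integer(channels_per_patient),
                 recording_minutes = recording_minutes,
                 seizure_free_fraction = seizure_free_fraction,
                 event_rates = event_rates, background_params = background_params,
                 amplitude_factor = amplitude_factor,
                 ehfo_morphology = ehfo_morphology,
                 artefact_params = artefact_params, label_noise = label_noise,
                 resected_fraction = resected_fraction, soz_fraction = soz_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

event_classes <- c("ripple", "fast_ripple", "hfo_with_spike",
                   "ringing_artefact", "noise_artefact")
hfo_classes <- c("ripple", "fast_ripple", "hfo_with_spike")

#' Generate 1/f coloured-noise background
#'
#' Zero-mean Gaussian noise whose power spectrum follows `1/f^alpha`,
#' synthesized by spectral shaping of white noise and scaled to the configured
#' RMS.  Deterministic for a given seed.
#'
#' @param n_samples Number of samples (> 0).
#' @param config A [sim_config()] object.
#' @param seed Integer seed; when `NULL` the current RNG stream is used.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_background <- function(n_samples, config, seed = NULL) {
  assert_that(is_count(n_samples), "n_samples must be a positive integer")
  gen <- function() {
    alpha <- config$background_params$alpha
    scale <- config$background_params$scale
    if (scale == 0) return(numeric(n_samples))
    white <- stats::rnorm(n_samples)
    xf <- stats::fft(white)
    freq <- c(0, seq_len(n_samples - 1)) / n_samples * config$sampling_rate
    # fold to two-sided frequency magnitudes
    freq <- pmin(freq, config$sampling_rate - freq)
    shape <- c(0, 1 / freq[-1]^(alpha / 2))
    x <- Re(stats::fft(xf * shape, inverse = TRUE)) / n_samples
    x <- x - mean(x)
    x * (scale / stats::sd(x))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Synthesize a single event waveform
#'
#' Produces the additive waveform for one ground-truth event.  Ripples and
#' fast ripples are Hann-windowed sinusoids; `hfo_with_spike` superimposes a
#' Gaussian-windowed monophasic spike transient; epileptogenic events receive
#' a broadband power boost within +/-45 ms of the event centre plus a 10-59 Hz
#' component spanning most of the 1-s analysis window; `ringing_artefact` is an
#' exponentially damped oscillation (the ringing of a filtered sharp
#' transient) with fewer than six resolvable peaks at detector scale;
#' `noise_artefact` is a Hann-windowed broadband noise burst.
#'
#' @param spec List or one-row data frame with at least `true_class`,
#'   `duration_ms`, `amplitude` and `epileptogenic`; optional `freq_hz`,
#'   `phase`, `polarity` pin the random morphology draws.
#' @param config A [sim_config()] object.
#' @return Numeric waveform vector with attribute `center_index` marking the
#'   sample aligned with the event centre.
#' @export
synthesize_event_waveform <- function(spec, config) {
  fs <- config$sampling_rate
  cls <- as.character(spec$true_class)
  assert_that(cls %in% event_classes, paste("unknown event class:", cls))
  dur_n <- max(2L, round(spec$duration_ms / 1000 * fs))
  amp <- spec$amplitude
  epi <- isTRUE(spec$epileptogenic)
  freq <- if (!is.null(spec$freq_hz) && !is.na(spec$freq_hz)) spec$freq_hz else {
    switch(cls,
           ripple = stats::runif(1, 85, 245),
           fast_ripple = stats::runif(1, 255, 480),
           hfo_with_spike = stats::runif(1, 85, 245),
           ringing_artefact = stats::runif(1, 100, 400),
           noise_artefact = NA_real_)
  }
  if (!is.na(freq)) assert_that(freq < fs / 2, "event frequency outside Nyquist range")
  phase <- if (!is.null(spec$phase) && !is.na(spec$phase)) spec$phase else stats::runif(1, 0, 2 * pi)
  pol <- if (!is.null(spec$polarity) && !is.na(spec$polarity)) spec$polarity else sample(c(-1, 1), 1)

  em <- config$ehfo_morphology
  # support length: long enough for spike transients and the epileptogenic
  # low-frequency envelope, always centred on the event centre
  L <- dur_n
  if (cls == "hfo_with_spike") L <- max(L, round(2.5 * em$spike_width_ms / 1000 * fs))
  if (epi) L <- max(L, round(em$lowfreq_envelope_ms / 1000 * fs))
  if (L %% 2L == 0L) L <- L + 1L
  ctr <- (L + 1L) %/% 2L
  t <- (seq_len(L) - ctr) / fs   # seconds relative to event centre
  w <- numeric(L)
  ev_idx <- which(abs(t) <= dur_n / fs / 2)
  tt <- t[ev_idx]
  hann <- 0.5 * (1 - cos(2 * pi * (seq_along(ev_idx) - 0.5) / length(ev_idx)))

  if (cls %in% c("ripple", "fast_ripple", "hfo_with_spike")) {
    osc <- amp * hann * sin(2 * pi * freq * tt + phase)
    if (epi) {
      boost <- sqrt(em$onset_boost)
      osc[abs(tt) <= 0.045] <- osc[abs(tt) <= 0.045] * boost
    }
    w[ev_idx] <- w[ev_idx] + osc
    if (cls == "hfo_with_spike") {
      sigma <- em$spike_width_ms / 1000 / 4.71  # FWHM ~ width/2
      w <- w + pol * em$spike_amplitude_factor * amp * exp(-0.5 * (t / sigma)^2)
    }
    if (epi) {
      # complementary-band tone within +/-45 ms: broadband onset signature
      f2 <- if (freq < 250) stats::runif(1, 280, 450) else stats::runif(1, 100, 220)
      on_idx <- which(abs(t) <= 0.045)
      h2 <- 0.5 * (1 - cos(2 * pi * (seq_along(on_idx) - 0.5) / length(on_idx)))
      w[on_idx] <- w[on_idx] + 0.7 * amp * h2 * sin(2 * pi * f2 * t[on_idx])
      # low-frequency component across the analysis window
      f3 <- stats::runif(1, 15, 50)
      env_n <- min(L, round(em$lowfreq_envelope_ms / 1000 * fs))
      lf_idx <- ctr + seq(-(env_n %/% 2), env_n %/% 2)
      lf_idx <- lf_idx[lf_idx >= 1 & lf_idx <= L]
      h3 <- 0.5 * (1 - cos(2 * pi * (seq_along(lf_idx) - 0.5) / length(lf_idx)))
      w[lf_idx] <- w[lf_idx] + em$lowfreq_amplitude_factor * amp * h3 *
        sin(2 * pi * f3 * t[lf_idx])
    }
  } else if (cls == "ringing_artefact") {
    tau <- config$artefact_params$ring_decay_cycles / freq
    ring <- amp * 1.2 * exp(-pmax(tt - tt[1], 0) / tau) * sin(2 * pi * freq * (tt - tt[1]))
    w[ev_idx] <- w[ev_idx] + ring
    sig_t <- config$artefact_params$transient_width_ms / 1000 / 2.355
    w <- w + pol * 2 * amp * exp(-0.5 * ((t - tt[1]) / sig_t)^2)
  } else { # noise_artefact
    w[ev_idx] <- w[ev_idx] + hann * stats::rnorm(length(ev_idx), sd = amp / 2)
  }
  attr(w, "center_index") <- ctr
  w
}

# band-passed (80-500 Hz) RMS of a signal; used to anchor event amplitudes
band_rms <- function(x, fs) {
  bp <- bandpass(x, 80, min(500, fs / 2 - 1), fs)
  sqrt(mean(bp^2))
}

#' Simulate a single 1-s analysis window
#'
#' Convenience generator for classifier experiments: one event of the given
#' class centred in a window of 1/f background, without building a full
#' recording.  Amplitude is anchored to the band-passed background RMS times
#' `config$amplitude_factor`.
#'
#' @param true_class One of `ripple`, `fast_ripple`, `hfo_with_spike`,
#'   `ringing_artefact`, `noise_artefact`, or `"background"` for no event.
#' @param epileptogenic Logical; apply the epileptogenic morphology.
#' @param config A [sim_config()] object.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @param n_samples Window length; defaults to one second of samples.
#' @param stray_spike Add a background interictal spike at a random off-centre
#'   position (150-450 ms from the window centre), unrelated to the event;
#'   such spikes are common in epileptic recordings and make spike/event
#'   co-occurrence (rather than mere spike presence) the class-defining
#'   feature.
#' @return List with `window` (numeric vector), and the drawn `duration_ms`,
#'   `amplitude`, `true_class`, `epileptogenic`.
#' @export
simulate_event_window <- function(true_class, epileptogenic = FALSE, config = sim_config(),
                                  seed = NULL, n_samples = NULL,
                                  stray_spike = FALSE) {
  run <- function() {
    fs <- config$sampling_rate
    n <- if (is.null(n_samples)) fs else n_samples
    bg <- generate_background(n, config)
    if (stray_spike) {
      em <- config$ehfo_morphology
      rms_b0 <- band_rms(bg, fs)
      off <- sample(c(-1, 1), 1) * stats::runif(1, 0.15, 0.45)
      t0 <- n %/% 2 + round(off * fs)
      sigma <- em$spike_width_ms / 1000 / 4.71 * fs
      tt <- seq_len(n) - t0
      bg <- bg + sample(c(-1, 1), 1) * em$spike_amplitude_factor *
        config$amplitude_factor * rms_b0 * exp(-0.5 * (tt / sigma)^2)
    }
    if (identical(true_class, "background")) {
      return(list(window = bg, true_class = "background",
                  epileptogenic = FALSE, duration_ms = NA, amplitude = NA))
    }
    rms_b <- band_rms(bg, fs)
    amp <- config$amplitude_factor * rms_b
    dur <- switch(true_class,
                  ripple = stats::runif(1, 60, 150),
                  fast_ripple = stats::runif(1, 40, 100),
                  hfo_with_spike = stats::runif(1, 60, 150),
                  ringing_artefact = stats::runif(1, 40, 100),
                  noise_artefact = stats::runif(1, 60, 150))
    # ensure enough oscillation cycles for the detector's peak criterion
    spec <- list(true_class = true_class, duration_ms = dur, amplitude = amp,
                 epileptogenic = epileptogenic)
    if (true_class %in% c("ripple", "hfo_with_spike"))
      spec$freq_hz <- stats::runif(1, max(85, 8 / (dur / 1000)), 245)
    if (true_class == "fast_ripple")
      spec$freq_hz <- stats::runif(1, max(255, 8 / (dur / 1000)), 480)
    w <- synthesize_event_waveform(spec, config)
    ctr <- attr(w, "center_index")
    mid <- n %/% 2
    idx <- mid - ctr + seq_along(w)
    keep <- idx >= 1 & idx <= n
    bg[idx[keep]] <- bg[idx[keep]] + w[keep]
    list(window = bg, true_class = true_class, epileptogenic = epileptogenic,
         duration_ms = dur, amplitude = amp)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a synthetic iEEG cohort
#'
#' Builds per-patient multichannel recordings with ground-truth events placed
#' by per-channel Poisson processes, channel metadata (resected / SOZ /
#' excluded flags) and 24-month surgical outcomes.  In seizure-free patients,
#' epileptogenic morphology is concentrated on resected channels: each
#' resected-channel HFO event is epileptogenic with probability
#' `1 - label_noise`, preserved-channel events are non-epileptogenic.  In
#' non-seizure-free patients the epileptogenic zone is incompletely resected,
#' so epileptogenic events appear on both resected (p = 0.5) and preserved
#' (p = 0.35) channels.
#'
#' @param config A [sim_config()] object.
#' @return List of class `hfo_cohort` with elements `recordings` (list of
#'   [hfo_recording] per patient), `events` (ground-truth data frame),
#'   `channels` (channel metadata), `outcomes` (per-patient outcome table) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config object")
  fs <- config$sampling_rate
  n <- round(config$recording_minutes * 60 * fs)
  total_rate <- sum(unlist(config$event_rates))
  # density cap: expected occupancy of 0.5 s exclusion zones must stay sparse
  assert_that(total_rate * 0.5 / 60 <= 0.3,
              "event rates imply overlapping events beyond the density cap",
              class = "epihfo_density_error")
  with_seed(config$seed, {
    n_free <- round(config$seizure_free_fraction * config$n_patients)
    sz_free <- rep(FALSE, config$n_patients)
    if (n_free > 0) sz_free[sample.int(config$n_patients, n_free)] <- TRUE
    pat_seeds <- sapply(seq_len(config$n_patients), function(p) child_seed(config$seed, p))

    recordings <- vector("list", config$n_patients)
    chan_tabs <- vector("list", config$n_patients)
    ev_tabs <- vector("list", config$n_patients)
    for (p in seq_len(config$n_patients)) {
      res <- with_seed(pat_seeds[p], simulate_patient(p, sz_free[p], n, config))
      recordings[[p]] <- res$recording
      chan_tabs[[p]] <- res$channels
      ev_tabs[[p]] <- res$events
    }
    events <- do.call(rbind, ev_tabs)
    rownames(events) <- NULL
    out <- structure(list(recordings = recordings,
                          events = events,
                          channels = do.call(rbind, chan_tabs),
                          outcomes = data.frame(patient = paste0("pt", seq_len(config$n_patients)),
                                                seizure_free = as.integer(sz_free)),
                          config = config),
                     class = "hfo_cohort")
    rownames(out$channels) <- NULL
    out
  })
}

simulate_patient <- function(p, seizure_free, n, config) {
  fs <- config$sampling_rate
  nch <- config$channels_per_patient
  pid <- paste0("pt", p)
  ch_names <- sprintf("ch%02d", seq_len(nch))
  n_soz <- max(1L, round(config$soz_fraction * nch))
  n_res <- max(n_soz, round(config$resected_fraction * nch))
  soz <- rep(FALSE, nch)
  soz[sample.int(nch, n_soz)] <- TRUE
  resected <- soz
  if (seizure_free) {
    # all SOZ channels resected plus anatomical margin
    extra <- setdiff(seq_len(nch), which(soz))
    resected[sample(extra, n_res - n_soz)] <- TRUE
  } else {
    # incomplete resection: half the SOZ left in place
    left <- which(soz)[seq_len(max(1L, n_soz %/% 2))]
    resected[left] <- FALSE
    extra <- setdiff(seq_len(nch), which(soz))
    resected[sample(extra, min(length(extra), n_res - sum(resected & soz)))] <- TRUE
  }
  sig <- matrix(0, nch, n)
  evs <- list()
  minutes <- n / fs / 60
  margin <- fs %/% 2 + 1L
  for (ch in seq_len(nch)) {
    bg <- generate_background(n, config)
    rms_b <- band_rms(bg, fs)
    centers_used <- numeric(0)
    for (cls in event_classes) {
      rate <- config$event_rates[[cls]]
      if (is.null(rate) || rate <= 0) next
      k <- stats::rpois(1, rate * minutes)
      if (k == 0) next
      for (i in seq_len(k)) {
        ctr <- NA
        for (try in 1:50) {
          cand <- sample(seq(margin, n - margin), 1)
          if (all(abs(cand - centers_used) >= 0.5 * fs)) { ctr <- cand; break }
        }
        if (is.na(ctr)) next
        centers_used <- c(centers_used, ctr)
        epi <- FALSE
        if (cls %in% hfo_classes) {
          pe <- if (seizure_free) {
            if (resected[ch]) 1 - config$label_noise else 0
          } else {
            if (resected[ch]) 0.5 else 0.35
          }
          epi <- stats::runif(1) < pe
        }
        dur <- switch(cls,
                      ripple = stats::runif(1, 60, 150),
                      fast_ripple = stats::runif(1, 40, 100),
                      hfo_with_spike = stats::runif(1, 60, 150),
                      ringing_artefact = stats::runif(1, 40, 100),
                      noise_artefact = stats::runif(1, 60, 150))
        amp <- config$amplitude_factor * rms_b
        spec <- list(true_class = cls, duration_ms = dur, amplitude = amp,
                     epileptogenic = epi)
        if (cls %in% c("ripple", "hfo_with_spike"))
          spec$freq_hz <- stats::runif(1, max(85, 8 / (dur / 1000)), 245)
        if (cls == "fast_ripple")
          spec$freq_hz <- stats::runif(1, max(255, 8 / (dur / 1000)), 480)
        w <- synthesize_event_waveform(spec, config)
        wctr <- attr(w, "center_index")
        idx <- ctr - wctr + seq_along(w)
        keep <- idx >= 1 & idx <= n
        sig[ch, idx[keep]] <- sig[ch, idx[keep]] + w[keep]
        dur_n <- round(dur / 1000 * fs)
        evs[[length(evs) + 1L]] <- data.frame(
          patient = pid, channel = ch_names[ch],
          onset_sample = ctr - dur_n %/% 2, duration_ms = dur,
          center_sample = ctr, true_class = cls,
          epileptogenic = epi, amplitude = amp)
      }
    }
    sig[ch, ] <- sig[ch, ] + bg
  }
  rec <- hfo_recording(sig, fs, ch_names, pid)
  channels <- data.frame(patient = pid, channel = ch_names,
                         resected = as.integer(resected),
                         soz = as.integer(soz), excluded = 0L)
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(patient = character(), channel = character(),
               onset_sample = integer(), duration_ms = numeric(),
               center_sample = integer(), true_class = character(),
               epileptogenic = logical(), amplitude = numeric())
  list(recording = rec, channels = channels, events = events)
}
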