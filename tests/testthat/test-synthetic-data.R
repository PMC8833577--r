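test_that("background generator is deterministic, zero at scale 0, and 1/f", {
  cfg <- tiny_sim()
  expect_identical(generate_background(5000, cfg, seed = 3),
                   generate_background(5000, cfg, seed = 3))
  cfg0 <- tiny_sim(background_params = list(alpha = 1, scale = 0))
  expect_identical(generate_background(1000, cfg0, seed = 1), numeric(1000))
  expect_error(generate_background(0, cfg), "positive")

  # log-log periodogram slope of alpha = 1 noise, fit by an independent
  # periodogram regression
  bg <- generate_background(120000, cfg, seed = 7)
  sp <- stats::spec.pgram(stats::ts(bg, frequency = 2000), plot = FALSE,
                          taper = 0)
  sel <- sp$freq > 1 & sp$freq < 900
  slope <- unname(stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.3)
})

test_that("event waveform durations follow the cycles/frequency arithmetic", {
  cfg <- tiny_sim()
  # ripple at 120 Hz, 8 cycles -> ~66.7 ms of oscillatory support
  spec <- list(true_class = "ripple", duration_ms = 8 / 120 * 1000,
               amplitude = 1, epileptogenic = FALSE, freq_hz = 120, phase = 0)
  w <- withr::with_seed(1, synthesize_event_waveform(spec, cfg))
  expect_equal(sum(w != 0) / cfg$sampling_rate * 1000, 8 / 120 * 1000,
               tolerance = 0.03)
  spec$true_class <- "fast_ripple"; spec$freq_hz <- 300
  spec$duration_ms <- 6 / 300 * 1000
  w2 <- withr::with_seed(1, synthesize_event_waveform(spec, cfg))
  expect_equal(sum(w2 != 0) / cfg$sampling_rate * 1000, 20, tolerance = 0.06)
  spec$freq_hz <- 1500
  expect_error(synthesize_event_waveform(spec, cfg), "Nyquist")
})

test_that("epileptogenic morphology adds low-frequency scalogram power", {
  cfg <- tiny_sim()
  sw_e <- simulate_event_window("hfo_with_spike", epileptogenic = TRUE,
                                config = cfg, seed = 11)
  sw_n <- simulate_event_window("hfo_with_spike", epileptogenic = FALSE,
                                config = cfg, seed = 11)
  # direct wavelet-transform oracle: rows below 60 Hz on the 224-row geometry
  sc_e <- compute_scalogram(sw_e$window, normalize = FALSE)
  sc_n <- compute_scalogram(sw_n$window, normalize = FALSE)
  freqs <- seq(500, 10, length.out = 224)
  low <- freqs < 60
  expect_gt(max(sc_e[low, ]), max(sc_n[low, ]))
})

test_that("cohorts respect rates, outcomes, overlap rule and determinism", {
  cfg <- sim_config(n_patients = 1, channels_per_patient = 8,
                    recording_minutes = 10, seizure_free_fraction = 1,
                    event_rates = list(ripple = 1), seed = 5)
  co <- generate_cohort(cfg)
  expect_true(all(co$events$true_class == "ripple"))
  # Poisson interval: 8 channels x 10 min x 1/min -> mean 80
  mu <- 8 * 10 * 1
  expect_lt(abs(nrow(co$events) - mu), 3 * sqrt(mu))
  # no artefact rows at artefact rate 0
  expect_false(any(grepl("artefact", co$events$true_class)))
  # 500 ms exclusion zone per channel
  by_ch <- split(co$events$center_sample, paste(co$events$patient, co$events$channel))
  gaps <- unlist(lapply(by_ch, function(v) diff(sort(v))))
  expect_true(all(gaps >= 0.5 * cfg$sampling_rate))
  # outcomes by construction + determinism on a small cohort
  cfg2 <- sim_config(n_patients = 4, channels_per_patient = 4,
                     recording_minutes = 1, seizure_free_fraction = 1, seed = 6)
  co1 <- generate_cohort(cfg2)
  co2 <- generate_cohort(cfg2)
  expect_true(all(co1$outcomes$seizure_free == 1))
  expect_identical(co1$events, co2$events)
  expect_identical(co1$recordings[[2]]$signal, co2$recordings[[2]]$signal)
  # density cap
  expect_error(generate_cohort(sim_config(event_rates = list(ripple = 100))),
               class = "epihfo_density_error")
})

test_that("epileptogenic labels on resected channels match 1 - label_noise", {
  cfg <- sim_config(n_patients = 2, channels_per_patient = 10,
                    recording_minutes = 8, seizure_free_fraction = 1,
                    event_rates = list(ripple = 0.6, hfo_with_spike = 0.6),
                    label_noise = 0.3, seed = 9)
  co <- generate_cohort(cfg)
  key <- paste(co$events$patient, co$events$channel)
  mkey <- paste(co$channels$patient, co$channels$channel)
  resected <- co$channels$resected[match(key, mkey)] > 0
  p_emp <- mean(co$events$epileptogenic[resected])
  n <- sum(resected)
  expect_lt(abs(p_emp - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  expect_false(any(co$events$epileptogenic[!resected]))
})

test_that("injected events stand above the in-band background RMS", {
  cfg <- tiny_sim(seed = 21)
  sw <- simulate_event_window("ripple", config = cfg, seed = 21)
  fs <- cfg$sampling_rate
  bp <- bandpass(sw$window, 80, 500, fs)
  mid <- (length(bp) %/% 2) + seq(-100, 100)
  bg_only <- simulate_event_window("background", config = cfg, seed = 21)
  bp_bg <- bandpass(bg_only$window, 80, 500, fs)
  expect_gt(max(abs(bp[mid])), 6 * sqrt(mean(bp_bg^2)))
  expect_gt(max(abs(bp[mid])) / max(abs(bp_bg)), 1.5)
})
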