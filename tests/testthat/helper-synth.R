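# Shared fixtures, all generated in code.

# small simulation config for fast tests
tiny_sim <- function(seed = 1L, ...) {
  sim_config(n_patients = 2, channels_per_patient = 4, recording_minutes = 1,
             seed = seed, ...)
}

# linearly separable two-class image stacks: class 1 carries a bright blob
toy_stacks <- function(n_per_class, size = 32, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- array(stats::rnorm(size * size * 3 * n, sd = 0.3),
               dim = c(size, size, 3, n))
    cls1 <- (n_per_class + 1):n
    lo <- max(2, round(size * 0.1)); hi <- round(size * 0.35)
    x[lo:hi, lo:hi, 1, cls1] <- x[lo:hi, lo:hi, 1, cls1] + 1.5
    list(x = x, y = rep(0:1, each = n_per_class))
  })
}

quick_cfg <- function(size = 32, epochs = 3, seed = 1L, ...) {
  classifier_config(backbone = "small_cnn", input_size = size, epochs = epochs,
                    seed = seed, ...)
}

# brute-force STE detector used as the independent oracle: literal
# re-implementation of the thresholding rules with plain loops
brute_ste <- function(x, fs, params = detection_params()) {
  bp <- bandpass(x, params$band_low, min(params$band_high, fs / 2 - 1), fs)
  w <- max(1L, round(params$rms_window_ms / 1000 * fs))
  n <- length(bp)
  # centred moving mean of squares via zoo, edges recomputed explicitly
  env <- sqrt(as.numeric(zoo::rollmean(zoo::zoo(bp^2), w, fill = NA,
                                       align = "center")))
  h_lo <- (w - 1L) %/% 2L; h_hi <- w - 1L - h_lo
  for (i in c(seq_len(min(n, w)), seq(max(1, n - w + 1), n))) {
    seg <- bp[max(1, i - h_lo):min(n, i + h_hi)]
    env[i] <- sqrt(mean(seg^2))
  }
  thr <- mean(env) + params$rms_threshold_sd * stats::sd(env)
  mask <- env > thr
  # runs
  runs <- list(); s <- NA
  for (i in seq_len(n)) {
    if (mask[i] && is.na(s)) s <- i
    if ((!mask[i] || i == n) && !is.na(s)) {
      e <- if (mask[i] && i == n) i else i - 1
      runs[[length(runs) + 1]] <- c(s, e); s <- NA
    }
  }
  gap <- round(params$merge_gap_ms / 1000 * fs)
  merged <- list()
  for (r in runs) {
    if (length(merged) && r[1] - merged[[length(merged)]][2] - 1 < gap)
      merged[[length(merged)]][2] <- r[2]
    else merged[[length(merged) + 1]] <- r
  }
  rect <- abs(bp)
  pthr <- mean(rect) + params$peak_threshold_sd * stats::sd(rect)
  min_len <- round(params$min_duration_ms / 1000 * fs)
  out <- list()
  for (r in merged) {
    if (r[2] - r[1] + 1 < min_len) next
    seg <- rect[r[1]:r[2]]
    np <- 0
    i <- 2
    while (i <= length(seg) - 1) {
      if (seg[i] > seg[i - 1]) {
        j <- i
        while (j < length(seg) && seg[j + 1] == seg[j]) j <- j + 1
        if (j < length(seg) && seg[j + 1] < seg[j]) {
          if (seg[i] > pthr) np <- np + 1
          i <- j + 1; next
        }
      }
      i <- i + 1
    }
    if (np >= params$min_peaks)
      out[[length(out) + 1]] <- c(start = r[1], end = r[2] + 1, n_peaks = np)
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      n_peaks = integer()))
  as.data.frame(do.call(rbind, out))
}

# inject Hann-windowed bursts into 1/f noise; returns recording + truth
injected_trace <- function(seed, n_bursts = 2, seconds = 60, fs = 2000,
                           amp_factor = 10) {
  cfg <- tiny_sim(seed = seed)
  bg <- generate_background(seconds * fs, cfg, seed = seed)
  rms_b <- sqrt(mean(bandpass(bg, 80, 500, fs)^2))
  centers <- round(seq(0.25, 0.75, length.out = n_bursts) * seconds * fs)
  truth <- data.frame(start = integer(), end = integer())
  x <- bg
  withr::with_seed(seed + 1000, {
    for (ctr in centers) {
      f <- stats::runif(1, 100, 400)
      cyc <- stats::runif(1, 10, 20)
      len <- round(cyc / f * fs)
      idx <- ctr + seq_len(len) - len %/% 2
      hann <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 0.5) / len))
      x[idx] <- x[idx] + amp_factor * rms_b * hann * sin(2 * pi * f * seq_len(len) / fs)
      truth <- rbind(truth, data.frame(start = idx[1], end = idx[len] + 1L))
    }
  })
  list(rec = hfo_recording(matrix(x, 1), fs, "ch01", paste0("p", seed)),
       truth = truth)
}
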