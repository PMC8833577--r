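#' Extract the 1-s analysis window around a candidate event
#'
#' Returns `fs` samples centred on the event (500 ms before and after the
#' centre at 2000 Hz).  Events whose window would cross a recording boundary
#' raise a `window-out-of-bounds` error and are expected to be dropped
#' upstream.
#'
#' @param rec An [hfo_recording].
#' @param event One-row data frame or list with `channel` and `center_sample`.
#' @return List of class `event_window` with `samples`, `center_sample`,
#'   `channel`, `patient_id`, `sampling_rate`.
#' @export
extract_window <- function(rec, event) {
  fs <- rec$sampling_rate
  half <- fs %/% 2
  ctr <- event$center_sample
  n <- ncol(rec$signal)
  assert_that(ctr - half >= 1 && ctr + half - 1 <= n,
              "event window exceeds recording boundary",
              class = "epihfo_window_oob")
  ch <- match(event$channel, rec$channel_names)
  assert_that(!is.na(ch), "event channel not present in recording")
  structure(list(samples = rec$signal[ch, (ctr - half):(ctr + half - 1)],
                 center_sample = ctr, channel = event$channel,
                 patient_id = rec$patient_id, sampling_rate = fs),
            class = "event_window")
}

as_event_window <- function(x, fs = 2000) {
  if (inherits(x, "event_window")) return(x)
  structure(list(samples = as.numeric(x), center_sample = NA_integer_,
                 channel = NA_character_, patient_id = NA_character_,
                 sampling_rate = fs),
            class = "event_window")
}

# complex Gabor (Morlet) transform of x at the requested frequencies, via
# frequency-domain multiplication with Gaussian kernels of `cycles` cycles
gabor_transform <- function(x, freqs, fs, cycles = 6) {
  n <- length(x)
  xf <- stats::fft(x)
  om <- (seq_len(n) - 1) / n * fs
  om[om > fs / 2] <- om[om > fs / 2] - fs   # two-sided frequency axis
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sigma_t <- cycles / (2 * pi * f)
    kern <- exp(-0.5 * (2 * pi * sigma_t * (om - f))^2)  # analytic: positive freqs only
    out[i, ] <- Mod(stats::fft(xf * kern, inverse = TRUE)) / n
  }
  out
}

#' Gabor-wavelet scalogram image
#'
#' Continuous Gabor-wavelet magnitude over `n_freqs` linearly spaced
#' frequencies from `fmin` to `fmax` Hz (default 10-500 Hz), with the time
#' axis box-averaged down to `n_cols` columns and the image min-max normalized
#' to `[0, 1]`.  Row 1 is the highest frequency (high frequencies at the top);
#' column 1 is the start of the window (-500 ms).
#'
#' @param window An `event_window` (or bare numeric vector).
#' @param fmin,fmax Frequency range in Hz; `fmax` must be below Nyquist.
#' @param n_freqs Number of frequency rows.
#' @param n_cols Number of time columns.
#' @param cycles Wavelet width in cycles (constant across frequencies).
#' @param normalize Min-max normalize per image (default `TRUE`).
#' @return `n_freqs` x `n_cols` matrix in `[0, 1]` with attributes recording
#'   the axis convention (`freq_range`, `time_range_ms`).
#' @export
compute_scalogram <- function(window, fmin = 10, fmax = 500, n_freqs = 224,
                              n_cols = n_freqs, cycles = 6, normalize = TRUE) {
  win <- as_event_window(window)
  fs <- win$sampling_rate
  assert_that(fmax < fs / 2, "fmax must be below the Nyquist frequency")
  freqs <- seq(fmax, fmin, length.out = n_freqs)  # row 1 = fmax
  mag <- gabor_transform(win$samples, freqs, fs, cycles)
  img <- mag %*% t(resample_weights(ncol(mag), n_cols))
  if (normalize) img <- normalize01(img)
  attr(img, "freq_range") <- c(fmin, fmax)
  attr(img, "time_range_ms") <- c(-0.5, 0.5) * length(win$samples) / fs * 1000
  img
}

normalize01 <- function(img) {
  rng <- range(img)
  if ((rng[2] - rng[1]) > 1e-12 * max(abs(rng), 1))
    (img - rng[1]) / (rng[2] - rng[1])
  else array(0.5, dim = dim(img))
}

#' EEG tracing plot
#'
#' The signal is min-max scaled into the 0-2000 range and drawn as a polyline
#' (stroke 1, background 0) on a 2000 x 2000 canvas -- one sample per canvas
#' column -- then box-averaged down to `size` x `size`.
#'
#' @param window An `event_window` (or numeric vector).
#' @param size Output image side length.
#' @param canvas Canvas side length (one canvas column per sample).
#' @return `size` x `size` matrix in `[0, 1]`; row 1 is the top of the canvas
#'   (largest signal values).
#' @export
render_tracing <- function(window, size = 224, canvas = NULL) {
  win <- as_event_window(window)
  x <- win$samples
  n <- length(x)
  if (is.null(canvas)) canvas <- n
  rng <- range(x)
  y <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) * (canvas - 1)
       else rep((canvas - 1) / 2, n)
  # per canvas column, the stroke spans from the midpoint with the previous
  # sample to the midpoint with the next (connected polyline)
  prev_mid <- c(y[1], (y[-n] + y[-1]) / 2)
  next_mid <- c((y[-n] + y[-1]) / 2, y[n])
  lo <- pmin(y, prev_mid, next_mid)
  hi <- pmax(y, prev_mid, next_mid) + 1  # stroke at least one pixel tall
  # row bins measured from the top of the canvas
  lo_top <- canvas - hi
  hi_top <- canvas - lo
  edges <- seq(0, canvas, length.out = size + 1)
  bin_h <- canvas / size
  # overlap of [lo_top, hi_top] with each row bin, one column at a time
  ov <- pmax(0, pmin(rep(hi_top, each = size), edges[-1]) -
                pmax(rep(lo_top, each = size), edges[-(size + 1)]))
  frac <- matrix(ov / bin_h, nrow = size)      # fraction of each row bin stroked
  img <- frac %*% t(resample_weights(n, size)) # box-average columns
  pmin(img, 1)
}

#' Amplitude-coding plot
#'
#' Each of the `size` columns carries a constant intensity equal to the
#' min-max-normalized mean signal value over that column's time bin, so the
#' image is exactly invertible to the bin-averaged normalized signal.
#' Constant windows map to a uniform 0.5 image.
#'
#' @param window An `event_window` (or numeric vector).
#' @param size Output image side length.
#' @return `size` x `size` matrix in `[0, 1]`.
#' @export
render_amplitude <- function(window, size = 224) {
  win <- as_event_window(window)
  x <- win$samples
  binned <- as.numeric(resample_weights(length(x), size) %*% x)
  rng <- range(binned)
  degenerate <- (rng[2] - rng[1]) <= 1e-12 * max(abs(rng), 1)
  vals <- if (!degenerate) (binned - rng[1]) / (rng[2] - rng[1]) else rep(0.5, size)
  matrix(rep(vals, each = size), nrow = size)
}

#' Encode an event window as the three feature images
#'
#' @param window An `event_window` (or numeric vector).
#' @param size Image side length (224 for the reference geometry; 64 for
#'   desk-scale experiments).
#' @return List of class `feature_images` with `scalogram`, `tracing`,
#'   `amplitude` matrices and `size`.
#' @export
encode_event <- function(window, size = 224) {
  win <- as_event_window(window)
  structure(list(scalogram = compute_scalogram(win, n_freqs = size, n_cols = size),
                 tracing = render_tracing(win, size = size),
                 amplitude = render_amplitude(win, size = size),
                 size = size,
                 provenance = list(patient = win$patient_id, channel = win$channel,
                                   center_sample = win$center_sample)),
            class = "feature_images")
}

#' Assemble the 3-plane network input for a task
#'
#' The artefact task uses the time-frequency information only, so the
#' scalogram is repeated on all three planes; the spike and eHFO tasks stack
#' (scalogram, tracing, amplitude) in that fixed order.
#'
#' @param features A `feature_images` object from [encode_event()].
#' @param task One of `"artefact"`, `"spike"`, `"ehfo"`.
#' @return `size` x `size` x 3 array.
#' @export
assemble_input <- function(features, task = c("artefact", "spike", "ehfo")) {
  task <- match.arg(task)
  s <- features$size
  out <- array(0, dim = c(s, s, 3))
  if (task == "artefact") {
    out[, , 1] <- features$scalogram
    out[, , 2] <- features$scalogram
    out[, , 3] <- features$scalogram
  } else {
    out[, , 1] <- features$scalogram
    out[, , 2] <- features$tracing
    out[, , 3] <- features$amplitude
  }
  out
}

#' Encode many windows into a batch array
#'
#' @param windows List of event windows (or numeric vectors).
#' @param task Input stacking task (see [assemble_input()]).
#' @param size Image side length.
#' @return `size` x `size` x 3 x N array plus a list of `feature_images`
#'   objects as attribute `features` when `keep_features = TRUE`.
#' @param keep_features Keep the per-event `feature_images` list.
#' @export
encode_batch <- function(windows, task = "spike", size = 64, keep_features = FALSE) {
  n <- length(windows)
  out <- array(0, dim = c(size, size, 3, n))
  feats <- if (keep_features) vector("list", n) else NULL
  for (i in seq_len(n)) {
    f <- encode_event(windows[[i]], size = size)
    out[, , , i] <- assemble_input(f, task)
    if (keep_features) feats[[i]] <- f
  }
  if (keep_features) attr(out, "features") <- feats
  out
}
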