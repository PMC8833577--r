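#' Pixel-wise significance template
#'
#' For every pixel, a one-tailed two-sample Welch t-test of the hypothesis
#' that the mean scalogram intensity of eHFOs exceeds that of non-eHFOs;
#' I(x, y) = 1 where p < alpha.  Pixels with zero variance in both groups are
#' set to 0 by convention.
#'
#' @param scalograms_ehfo,scalograms_non 3-d arrays (rows x cols x events) of
#'   per-event scalogram images for the two classes (n >= 2 each).
#' @param alpha Per-pixel significance level.
#' @return Binary matrix (rows x cols) of class `significance_template`.
#' @export
pixelwise_template <- function(scalograms_ehfo, scalograms_non, alpha = 0.005) {
  da <- dim(scalograms_ehfo); db <- dim(scalograms_non)
  assert_that(length(da) == 3 && length(db) == 3 && all(da[1:2] == db[1:2]),
              "inputs must be rows x cols x events arrays of matching geometry")
  n1 <- da[3]; n2 <- db[3]
  assert_that(n1 >= 2 && n2 >= 2, "each group needs at least two images")
  a <- matrix(scalograms_ehfo, ncol = n1)
  b <- matrix(scalograms_non, ncol = n2)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- stats::pt(t, df, lower.tail = FALSE)
  sig <- !is.na(p) & p < alpha      # zero variance in both groups -> NA -> 0
  out <- matrix(as.integer(sig), da[1], da[2])
  class(out) <- c("significance_template", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Population template from per-patient binaries
#'
#' @param templates List of per-patient binary significance templates.
#' @return Matrix in `[0, 1]`: the mean of the individual binary images.
#' @export
population_template <- function(templates) {
  assert_that(length(templates) >= 1, "at least one template required")
  Reduce(`+`, lapply(templates, unclass)) / length(templates)
}

#' Build the inverted-T binary mask
#'
#' Union of a vertical stroke (all frequencies within the time bounds) and a
#' horizontal stroke (the low-frequency band across the whole time axis) on
#' the scalogram geometry (linear frequency axis, row 1 = `f_range[2]`,
#' column 1 = `t_range[1]`).  Rectangle indices are rounded outward so the
#' stated physical bounds are fully covered.
#'
#' @param time_bounds_ms Time bounds of the vertical stroke, ms relative to
#'   the window centre (default -45..45).
#' @param freq_bounds_hz Frequency bounds of the horizontal stroke (default
#'   10..59 Hz).
#' @param n_rows,n_cols Image geometry.
#' @param t_range_ms,f_range_hz Full axis ranges of the image.
#' @return Logical matrix mask.
#' @export
build_inverted_t_mask <- function(time_bounds_ms = c(-45, 45),
                                  freq_bounds_hz = c(10, 59),
                                  n_rows = 224, n_cols = 224,
                                  t_range_ms = c(-500, 500),
                                  f_range_hz = c(10, 500)) {
  assert_that(time_bounds_ms[1] >= t_range_ms[1] && time_bounds_ms[2] <= t_range_ms[2],
              "time bounds outside the image time axis")
  assert_that(freq_bounds_hz[1] >= f_range_hz[1] && freq_bounds_hz[2] <= f_range_hz[2],
              "frequency bounds outside the image frequency axis")
  cols <- outward_bins(time_bounds_ms, t_range_ms, n_cols)
  # frequency axis runs top-down from f_range[2] to f_range[1]
  rows <- outward_bins(rev(f_range_hz[2] + f_range_hz[1] - freq_bounds_hz),
                       f_range_hz, n_rows)
  mask <- matrix(FALSE, n_rows, n_cols)
  mask[, cols[1]:cols[2]] <- TRUE
  mask[rows[1]:rows[2], ] <- TRUE
  mask
}

# 1-based inclusive bin range covering [bounds] on an axis of n bins spanning
# rng, rounded outward
outward_bins <- function(bounds, rng, n) {
  pos <- (bounds - rng[1]) / (rng[2] - rng[1]) * n
  lo <- max(1L, floor(pos[1]) + 1L)
  hi <- min(n, if (pos[2] == floor(pos[2])) floor(pos[2]) else floor(pos[2]) + 1L)
  c(lo, hi)
}

#' Perturb a scalogram towards the eHFO signature
#'
#' Inside the mask each pixel becomes `0.5 * value + 0.5 * max(image)`;
#' pixels outside the mask are untouched (the other input planes are never
#' modified).
#'
#' @param image Normalized scalogram matrix.
#' @param mask Logical matrix of the same shape.
#' @return Perturbed image.
#' @export
perturb_scalogram <- function(image, mask) {
  assert_that(all(dim(image) == dim(mask)), "image and mask shapes differ")
  out <- image
  out[mask] <- 0.5 * image[mask] + 0.5 * max(image)
  out
}

#' Time-domain characteristic pattern (TDCP)
#'
#' Unit-amplitude Gaussian-windowed monophasic deflection of the stated
#' width: the support spans `width_ms` and the full width at half maximum is
#' about `width_ms / 2`.  Upgoing patterns are positive, downgoing negative.
#'
#' @param direction `"upgoing"` or `"downgoing"`.
#' @param width_ms Support width in ms.
#' @param fs Sampling rate (samples per second of the pattern).
#' @return Numeric waveform of `width_ms * fs / 1000` samples, peak at the
#'   centre.
#' @export
make_tdcp <- function(direction = c("upgoing", "downgoing"), width_ms = 60,
                      fs = 2000) {
  direction <- match.arg(direction)
  n <- max(3L, round(width_ms / 1000 * fs))
  if (n %% 2L == 0L) n <- n + 1L   # keep one sample exactly at the peak
  t <- seq_len(n) - (n + 1) / 2
  sigma <- (width_ms / 1000 * fs) / 2 / 2.355  # FWHM = width/2
  g <- exp(-0.5 * (t / sigma)^2)
  if (direction == "downgoing") -g else g
}

#' Insert a TDCP into an amplitude-coding image
#'
#' The columns under the pattern footprint are replaced by the scaled TDCP:
#' the pattern's own min-max-normalized intensity profile is mapped onto the
#' plot's intensity range, so an upgoing pattern rises from the plot minimum
#' to a peak equal to the maximum value in the whole plot, and a downgoing
#' pattern falls from the plot maximum to a valley equal to the minimum.
#' All other columns (and all other input planes) are unchanged.
#'
#' @param image Amplitude-coding matrix (`size x size`).
#' @param direction `"upgoing"` or `"downgoing"`.
#' @param position Centre column (1-based) for the insertion.
#' @param width_ms Pattern width in ms.
#' @param window_ms Time span of the image in ms.
#' @return Perturbed image.
#' @export
insert_tdcp <- function(image, direction = c("upgoing", "downgoing"),
                        position, width_ms = 60, window_ms = 1000) {
  direction <- match.arg(direction)
  size <- ncol(image)
  fcols <- max(3L, round(width_ms / window_ms * size))
  if (fcols %% 2L == 0L) fcols <- fcols + 1L
  half <- fcols %/% 2L
  assert_that(position - half >= 1 && position + half <= size,
              "TDCP footprint exceeds the image", class = "epihfo_oob_position")
  g <- abs(make_tdcp(direction, width_ms = fcols, fs = 1000))  # fcols samples
  lo <- min(image); hi <- max(image)
  vals <- if (direction == "upgoing") lo + g * (hi - lo)
          else hi - g * (hi - lo)
  out <- image
  cols <- (position - half):(position + half)
  out[, cols] <- matrix(rep(vals, each = nrow(image)), nrow = nrow(image))
  out
}

#' Exhaustive TDCP placement scan for one event
#'
#' Evaluates the model's probability change when the TDCP is inserted at
#' every admissible column of the amplitude-coding plane (other planes kept
#' fixed) and reports the placement with the maximum change (first occurrence
#' on ties).
#'
#' @param model A trained eHFO `hfo_cnn` (frozen-backbone head model).
#' @param stack `S x S x 3` spike-task input for the event (plane 3 =
#'   amplitude-coding).
#' @param direction TDCP direction.
#' @param width_ms Pattern width.
#' @param stride Column stride of the search (1 = exhaustive).
#' @param window_ms Image time span.
#' @return List with `delta` (max probability change), `position_col`,
#'   `position_ms` (relative to centre), `p_original`, and the per-position
#'   `deltas`.
#' @export
scan_tdcp <- function(model, stack, direction = "upgoing", width_ms = 60,
                      stride = 1L, window_ms = 1000) {
  size <- dim(stack)[1]
  fcols <- max(3L, round(width_ms / window_ms * size))
  if (fcols %% 2L == 0L) fcols <- fcols + 1L
  half <- fcols %/% 2L
  positions <- seq(1L + half, size - half, by = stride)
  batch <- array(0, dim = c(size, size, 3, length(positions) + 1L))
  batch[, , , 1] <- stack
  for (i in seq_along(positions)) {
    s <- stack
    s[, , 3] <- insert_tdcp(stack[, , 3], direction, positions[i], width_ms,
                            window_ms)
    batch[, , , i + 1L] <- s
  }
  p <- predict(model, batch)
  deltas <- p[-1] - p[1]
  best <- which.max(deltas)
  list(delta = deltas[best], position_col = positions[best],
       position_ms = (positions[best] - 0.5) / size * window_ms - window_ms / 2,
       p_original = p[1], deltas = deltas, positions = positions)
}

#' Summarise a perturbation experiment
#'
#' Applies a perturbation to each event, collects the probability changes,
#' and tests H1: mean change > 0 with a one-sample one-tailed t-test.
#'
#' @param deltas Numeric vector of probability changes (one per event).
#' @param patients Optional patient id per event for per-patient histograms.
#' @return List with `mean`, `sd`, `t`, `p_value`, `n`, and `by_patient`
#'   (list of per-patient delta vectors).
#' @export
perturbation_study <- function(deltas, patients = NULL) {
  assert_that(length(deltas) >= 2, "at least two events required")
  m <- mean(deltas); s <- stats::sd(deltas)
  if (s == 0) {
    tt <- list(statistic = c(t = if (m > 0) Inf else 0),
               p.value = if (m > 0) 0 else 1)
  } else {
    tt <- stats::t.test(deltas, mu = 0, alternative = "greater")
  }
  by_pat <- if (!is.null(patients)) split(deltas, patients) else NULL
  list(mean = m, sd = s, t = unname(tt$statistic), p_value = tt$p.value,
       n = length(deltas), by_patient = by_pat)
}

#' Probability change under scalogram perturbation for a batch of events
#'
#' @param model Trained eHFO model (frozen backbone head model).
#' @param stacks `S x S x 3 x N` spike-task inputs.
#' @param mask Logical mask matrix (e.g. [build_inverted_t_mask()] at the
#'   stack geometry).
#' @return Numeric vector of probability changes.
#' @export
perturb_scalogram_batch <- function(model, stacks, mask) {
  n <- dim(stacks)[4]
  pert <- stacks
  for (i in seq_len(n))
    pert[, , 1, i] <- perturb_scalogram(stacks[, , 1, i], mask)
  predict(model, pert) - predict(model, stacks)
}
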