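test_that("window extraction follows the index arithmetic and bounds", {
  rec <- hfo_recording(matrix(seq_len(10000), 1, byrow = TRUE), 2000, "c1", "p")
  w <- extract_window(rec, list(channel = "c1", center_sample = 5000))
  expect_length(w$samples, 2000)
  expect_equal(w$samples[1], 4000)
  expect_equal(w$samples[2000], 5999)
  expect_error(extract_window(rec, list(channel = "c1", center_sample = 300)),
               class = "epihfo_window_oob")
  expect_error(extract_window(rec, list(channel = "c1", center_sample = 9500)),
               class = "epihfo_window_oob")
})

test_that("scalogram localizes tones to the right rows and is scale invariant", {
  t <- (0:1999) / 2000
  freqs <- seq(500, 10, length.out = 224)
  bin <- abs(diff(freqs[1:2]))
  sc <- compute_scalogram(sin(2 * pi * 100 * t))
  ij <- which(sc == max(sc), arr.ind = TRUE)[1, ]
  expect_lt(abs(freqs[ij[1]] - 100), bin + 1e-9)
  # two tones -> two ridge rows
  sc2 <- compute_scalogram(sin(2 * pi * 100 * t) + sin(2 * pi * 400 * t),
                           normalize = FALSE)
  rowmax <- apply(sc2[, 80:140], 1, max)  # central columns, away from edges
  ord <- order(rowmax, decreasing = TRUE)
  ridge_freqs <- sort(freqs[ord[1:2]])
  # local maxima rows near each tone
  near100 <- which(abs(freqs - 100) < 3 * bin)
  near400 <- which(abs(freqs - 400) < 3 * bin)
  expect_gt(max(rowmax[near100]), stats::median(rowmax) * 2)
  expect_gt(max(rowmax[near400]), stats::median(rowmax) * 2)
  # min-max normalization removes scale
  x <- stats::rnorm(2000)
  expect_equal(compute_scalogram(x), compute_scalogram(10 * x))
})

test_that("scalogram localization holds over random time-frequency draws", {
  fs <- 2000
  freqs <- seq(500, 10, length.out = 224)
  for (s in 1:10) {
    withr::with_seed(300 + s, {
      f <- stats::runif(1, 60, 450)
      ctr <- stats::runif(1, 0.25, 0.75)  # fraction of the window
      len <- round(12 / f * fs)
      x <- stats::rnorm(fs) * 1e-3
      idx <- round(ctr * fs) + seq_len(len) - len %/% 2
      hann <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 0.5) / len))
      x[idx] <- x[idx] + hann * sin(2 * pi * f * seq_len(len) / fs)
      sc <- compute_scalogram(x)
      ij <- which(sc == max(sc), arr.ind = TRUE)[1, ]
      expect_lt(abs(ij[2] - ctr * 224), 2 + 1)       # within +/-2 columns
      expect_lt(abs(freqs[ij[1]] - f), 2 * abs(diff(freqs[1:2])))  # +/-1 row
    })
  }
})

test_that("tracing plot follows the canvas conventions", {
  # constant signal -> single horizontal stroke at mid height
  tr <- render_tracing(rep(1, 2000), 224)
  rows_hit <- which(rowSums(tr) > 0)
  expect_lte(diff(range(rows_hit)), 1)
  expect_lt(abs(mean(rows_hit) - 112.5), 2)
  # linear ramp -> anti-diagonal (rising signal drawn bottom-left to top-right)
  tr2 <- render_tracing(seq(0, 1, length.out = 2000), 224)
  cent <- sapply(1:224, function(j) {
    col <- tr2[, j]; sum(seq_along(col) * col) / sum(col)
  })
  expect_lt(max(abs(cent - rev(seq_len(224) - 0.5) - 0.5)), 2)
  # centroid round trip on a resolvable band-limited signal
  t <- (0:1999) / 2000
  x <- sin(2 * pi * 7 * t) + 0.5 * sin(2 * pi * 23 * t)
  tr3 <- render_tracing(x, 224)
  cent3 <- sapply(1:224, function(j) {
    col <- tr3[, j]; sum(seq_along(col) * col) / sum(col)
  })
  y <- (x - min(x)) / (max(x) - min(x))
  yb <- as.numeric(epihfo:::resample_weights(2000, 224) %*% y)
  expect_lt(mean(abs(cent3 - (224.5 - yb * 223))), 2)
})

test_that("amplitude plot is exactly invertible and handles degenerate input", {
  x <- withr::with_seed(5, stats::rnorm(2000))
  am <- render_amplitude(x, 64)
  # every column is constant
  expect_equal(max(apply(am, 2, function(c) diff(range(c)))), 0)
  binned <- as.numeric(epihfo:::resample_weights(2000, 64) %*% x)
  nb <- (binned - min(binned)) / (max(binned) - min(binned))
  expect_identical(am[1, ], nb)
  expect_equal(min(am), 0)
  expect_equal(max(am), 1)
  expect_true(all(render_amplitude(rep(3, 2000), 32) == 0.5))
})

test_that("input stacks follow the per-task plane conventions", {
  f <- encode_event(withr::with_seed(6, stats::rnorm(2000)), size = 64)
  art <- assemble_input(f, "artefact")
  expect_identical(art[, , 1], art[, , 2])
  expect_identical(art[, , 1], art[, , 3])
  expect_equal(art[, , 1], f$scalogram, ignore_attr = TRUE)
  spk <- assemble_input(f, "spike")
  expect_equal(spk[, , 2], f$tracing, ignore_attr = TRUE)
  expect_equal(spk[, , 3], f$amplitude, ignore_attr = TRUE)
  expect_equal(dim(spk), c(64, 64, 3))
  expect_error(assemble_input(f, "nonsense"))
  # encoders are pure functions
  f2 <- encode_event(withr::with_seed(6, stats::rnorm(2000)), size = 64)
  expect_identical(f, f2)
})
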