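# small frozen-backbone model whose head is trained on toy features; used to
# exercise the perturbation machinery cheaply
toy_ehfo_model <- function(size = 32, seed = 40) {
  ts <- toy_stacks(30, size = size, seed = seed)
  cfg <- quick_cfg(size = size, epochs = 3, seed = seed + 1)
  train_classifier(ts$x[, , , 1:50, drop = FALSE], ts$y[1:50], cfg,
                   ts$x[, , , 51:60, drop = FALSE], ts$y[51:60])$model
}

test_that("pixelwise template controls false positives and finds planted signal", {
  withr::with_seed(50, {
    a <- array(stats::rnorm(40 * 40 * 60), dim = c(40, 40, 60))
    b <- array(stats::rnorm(40 * 40 * 60), dim = c(40, 40, 60))
  })
  null_tpl <- pixelwise_template(a, b, alpha = 0.005)
  expect_lte(mean(null_tpl), 2 * 0.005)
  # planted 3-sigma rectangle
  a2 <- a; a2[10:20, 15:30, ] <- a2[10:20, 15:30, ] + 3
  tpl <- pixelwise_template(a2, b, alpha = 0.005)
  expect_gte(mean(tpl[10:20, 15:30]), 0.95)
  outside <- tpl; outside[10:20, 15:30] <- NA
  expect_lte(mean(outside, na.rm = TRUE), 0.01)
  # one-tailed direction: swapping the groups empties the rectangle
  tpl_sw <- pixelwise_template(b, a2, alpha = 0.005)
  expect_lte(mean(tpl_sw[10:20, 15:30]), 0.01)
  # zero variance in both groups -> 0 by convention
  z <- array(1, dim = c(4, 4, 5))
  expect_true(all(pixelwise_template(z, z) == 0))
  # population average of binaries
  pop <- population_template(list(tpl, null_tpl))
  expect_true(all(pop >= 0 & pop <= 1))
  expect_equal(pop, (unclass(tpl) + unclass(null_tpl)) / 2, ignore_attr = TRUE)
})

test_that("template false-positive rate holds under label permutation", {
  withr::with_seed(51, {
    pool <- array(stats::rnorm(30 * 30 * 40), dim = c(30, 30, 40))
    fracs <- replicate(20, {
      idx <- sample(40)
      mean(pixelwise_template(pool[, , idx[1:20]], pool[, , idx[21:40]],
                              alpha = 0.005))
    })
  })
  expect_lte(mean(fracs), 2 * 0.005)
})

test_that("inverted-T mask geometry follows outward-rounded index arithmetic", {
  m <- build_inverted_t_mask()
  vert_cols <- which(apply(m[1:5, , drop = FALSE], 2, all))
  horz_rows <- which(apply(m[, 1:5, drop = FALSE], 1, all))
  # own derivation: (-45+500)/1000*224 = 101.92 -> col 102 (1-based);
  # (45+500)/1000*224 = 122.08 -> col 123
  expect_equal(range(vert_cols), c(102, 123))
  # 10-59 Hz on the top-down 10-500 Hz axis -> bottom 23 rows
  expect_equal(range(horz_rows), c(202, 224))
  expect_equal(length(horz_rows), 23)
  # area identity: union = vertical + horizontal - overlap
  nv <- length(vert_cols) * 224
  nh <- length(horz_rows) * 224
  expect_equal(sum(m), nv + nh - length(vert_cols) * length(horz_rows))
  expect_error(build_inverted_t_mask(time_bounds_ms = c(-600, 0)), "outside")
})

test_that("scalogram perturbation follows the half-max formula locally", {
  img <- withr::with_seed(52, matrix(stats::runif(64 * 64), 64))
  mask <- matrix(FALSE, 64, 64); mask[10:20, 30:40] <- TRUE
  out <- perturb_scalogram(img, mask)
  expect_equal(out[mask], 0.5 * img[mask] + 0.5 * max(img))
  expect_identical(out[!mask], img[!mask])
  # a pixel already at the max is a fixed point
  img2 <- img; img2[15, 35] <- max(img)
  expect_equal(perturb_scalogram(img2, mask)[15, 35], max(img2))
  # repeated application approaches the max monotonically, never passing it
  o1 <- perturb_scalogram(img, mask); o2 <- perturb_scalogram(o1, mask)
  expect_true(all(o2[mask] >= o1[mask] - 1e-12))
  expect_true(all(o2[mask] <= max(img) + 1e-12))
})

test_that("TDCP templates are symmetric with the stated width", {
  up <- make_tdcp("upgoing", width_ms = 60, fs = 2000)
  dn <- make_tdcp("downgoing", width_ms = 60, fs = 2000)
  expect_equal(up, -dn)
  expect_equal(which.max(up), (length(up) + 1) %/% 2, tolerance = 1)
  fwhm_ms <- sum(up >= 0.5) / 2000 * 1000
  expect_equal(fwhm_ms, 30, tolerance = 0.1 * 30)
  expect_equal(max(up), 1)
})

test_that("TDCP insertion scales to the plot extremes and stays local", {
  am <- render_amplitude(withr::with_seed(53, stats::rnorm(2000)), 64)
  up <- insert_tdcp(am, "upgoing", position = 32)
  expect_equal(max(up), max(am))
  dn <- insert_tdcp(am, "downgoing", position = 32)
  expect_equal(min(dn), min(am))
  fcols <- max(3L, round(60 / 1000 * 64)); if (fcols %% 2 == 0) fcols <- fcols + 1
  half <- fcols %/% 2
  untouched <- setdiff(1:64, (32 - half):(32 + half))
  expect_identical(up[, untouched], am[, untouched])
  expect_error(insert_tdcp(am, "upgoing", position = 1),
               class = "epihfo_oob_position")
})

test_that("TDCP scanning is exhaustive and ignores dead input planes", {
  model <- toy_ehfo_model(size = 32)
  stack <- toy_stacks(1, size = 32, seed = 60)$x[, , , 1]
  sc <- scan_tdcp(model, stack, "upgoing", width_ms = 60, stride = 1L)
  # brute-force oracle: re-evaluate every admissible column independently
  p0 <- predict(model, stack)
  for (k in seq(1, length(sc$positions), by = 7)) {
    s2 <- stack
    s2[, , 3] <- insert_tdcp(stack[, , 3], "upgoing", sc$positions[k], 60, 1000)
    expect_equal(sc$deltas[k], predict(model, s2) - p0, tolerance = 1e-12)
  }
  expect_equal(sc$delta, max(sc$deltas))
  # kill the amplitude plane: zero the plane-3 slice of the first conv filters
  dead <- model
  for (li in seq_along(dead$backbone)) {
    if (dead$backbone[[li]]$type == "conv") {
      dead$backbone[[li]]$params$w[, , 3, ] <- 0
      break
    }
  }
  sc2 <- scan_tdcp(dead, stack, "upgoing")
  expect_true(all(abs(sc2$deltas) < 1e-12))
})

test_that("perturbation summaries match direct recomputation", {
  expect_equal(perturbation_study(rep(0, 10))$mean, 0)
  expect_equal(perturbation_study(rep(0, 10))$p_value, 1)
  s <- perturbation_study(rep(0.3, 10))
  expect_equal(s$mean, 0.3)
  expect_lt(s$p_value, 1e-10)
  withr::with_seed(61, d <- stats::rnorm(40, 0.1, 0.2))
  pats <- rep(c("a", "b"), 20)
  ps <- perturbation_study(d, pats)
  tt <- stats::t.test(d, mu = 0, alternative = "greater")
  expect_equal(ps$mean, mean(d))
  expect_equal(ps$sd, stats::sd(d))
  expect_equal(ps$p_value, tt$p.value)
  expect_equal(ps$t, unname(tt$statistic))
  expect_identical(ps$by_patient, split(d, pats))
})
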