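weak_fixture <- function() {
  channels <- data.frame(patient = rep(c("p1", "p2"), each = 3),
                         channel = rep(c("c1", "c2", "c3"), 2),
                         resected = c(1, 1, 0, 1, 0, 0),
                         soz = c(1, 0, 0, 1, 0, 0))
  outcomes <- data.frame(patient = c("p1", "p2"), seizure_free = c(1, 0))
  events <- data.frame(patient = rep(c("p1", "p2"), each = 3),
                       channel = rep(c("c1", "c2", "c3"), 2))
  list(channels = channels, outcomes = outcomes, events = events)
}

test_that("weak labels follow the resection/SOZ/outcome rules", {
  fx <- weak_fixture()
  wl <- assign_weak_labels(fx$events, fx$channels, fx$outcomes)
  # resected SOZ channel -> y = 1, w = 1
  expect_equal(wl$y[1], 1); expect_equal(wl$w[1], 1)
  # resected non-SOZ channel -> y = 1, w = 0.5
  expect_equal(wl$y[2], 1); expect_equal(wl$w[2], 0.5)
  # preserved channel -> y = 0, w = 1
  expect_equal(wl$y[3], 0); expect_equal(wl$w[3], 1)
  # only seizure-free patients are eligible for training
  expect_identical(wl$eligible_for_training, rep(c(TRUE, FALSE), each = 3))
  bad <- fx$events; bad$channel[1] <- "nope"
  expect_error(assign_weak_labels(bad, fx$channels, fx$outcomes),
               class = "epihfo_label_error")
})

test_that("artefact filtering matches a brute-force threshold scan", {
  ev <- data.frame(patient = "p", channel = paste0("c", 1:10))
  expect_equal(nrow(filter_artifacts(ev, rep(1, 10))), 10)
  expect_equal(nrow(filter_artifacts(ev, rep(0, 10))), 0)
  p <- withr::with_seed(2, stats::runif(10))
  kept <- filter_artifacts(ev, p, threshold = 0.5)
  expect_identical(kept$channel, ev$channel[which(p >= 0.5)])
  expect_identical(kept$real_hfo_prob, p[p >= 0.5])
})

test_that("per-patient capping keeps small patients whole and samples the rest", {
  ev <- data.frame(patient = rep(c("a", "b"), c(1800, 5000)))
  idx <- cap_sample_per_patient(ev, cap = 2500, seed = 3)
  expect_equal(sum(ev$patient[idx] == "a"), 1800)
  expect_equal(sum(ev$patient[idx] == "b"), 2500)
  expect_false(anyDuplicated(idx) > 0)
  expect_identical(idx, cap_sample_per_patient(ev, cap = 2500, seed = 3))
  expect_error(cap_sample_per_patient(ev, cap = 0), "at least 1")
})

test_that("patient-specific splits use the seizure-free pool without leakage", {
  outcomes <- data.frame(patient = paste0("p", 1:12),
                         seizure_free = c(rep(1, 9), rep(0, 3)))
  events <- data.frame(patient = rep(outcomes$patient, each = 5),
                       channel = "c1")
  events$eligible_for_training <- events$patient %in% paste0("p", 1:9)
  # seizure-free target: pool = the other 8 seizure-free patients
  sel <- build_patient_specific_split(events, outcomes, "p1")
  expect_setequal(unique(events$patient[sel]), paste0("p", 2:9))
  # non-seizure-free target: pool = all 9 seizure-free patients
  sel2 <- build_patient_specific_split(events, outcomes, "p10")
  expect_setequal(unique(events$patient[sel2]), paste0("p", 1:9))
  expect_false(any(events$patient[sel] == "p1"))
  expect_error(build_patient_specific_split(events, outcomes, "p99"),
               "not in cohort")
})

test_that("the eHFO trainer freezes the spike backbone and honours weights", {
  ts <- toy_stacks(30, size = 32, seed = 20)
  cfg <- quick_cfg(size = 32, epochs = 3, seed = 21)
  spike <- train_classifier(ts$x[, , , 1:50, drop = FALSE], ts$y[1:50], cfg,
                            ts$x[, , , 51:60, drop = FALSE], ts$y[51:60])$model
  wl_y <- ts$y
  wl_w <- rep(c(1, 0.5), length.out = length(wl_y))
  dm <- train_dlatrev(ts$x, wl_y, wl_w, spike, cfg)
  # backbone parameters bit-identical before and after
  expect_identical(epihfo:::get_model_state(dm$model)$bb_params,
                   epihfo:::get_model_state(spike)$bb_params)
  expect_true(dm$model$frozen)
  expect_equal(dm$record$selected_epoch,
               select_checkpoint(dm$record$val_loss, "global_min"))
  # same seed twice reproduces the loss trajectory exactly
  d1 <- train_dlatrev(ts$x, wl_y, wl_w, spike, cfg)
  expect_identical(d1$record$train_loss, dm$record$train_loss)
  expect_identical(d1$record$val_loss, dm$record$val_loss)
  # discovery yields one labelled probability per event
  disc <- discover_ehfos(dm, ts$x)
  expect_equal(nrow(disc), length(wl_y))
  expect_true(all(disc$class %in% c("eHFO", "non-eHFO")))
  expect_identical(disc$class == "eHFO", disc$probability >= 0.5)
  disc2 <- discover_ehfos(dm, ts$x)
  expect_identical(disc, disc2)
})

test_that("raising the weight of a subpopulation raises its gradient share", {
  withr::with_seed(30, {
    p <- stats::runif(40, 0.05, 0.95)
    y <- stats::rbinom(40, 1, 0.5)
  })
  sub <- 1:10
  grad_norm <- function(w_sub) {
    w <- rep(1, 40); w[sub] <- w_sub
    g <- w * (p - y) / 40      # d(mean weighted BCE)/d logit
    sqrt(sum(g[sub]^2))
  }
  expect_gt(grad_norm(1.0), grad_norm(0.5))
  expect_gt(grad_norm(2.0), grad_norm(1.0))
})
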