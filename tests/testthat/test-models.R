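test_that("weighted BCE matches hand-computed values and plain BCE at w = 1", {
  expect_equal(weighted_bce(0.5, 1, 1), 0.693147, tolerance = 1e-5)
  expect_equal(weighted_bce(0.5, 1, 0.5), 0.346574, tolerance = 1e-5)
  expect_lt(weighted_bce(1 - 1e-7, 1, 1), 1e-6)
  expect_error(weighted_bce(0.5, 1, 0), "positive")
  # w = 1 equals the standard binary cross-entropy on 1000 random pairs
  withr::with_seed(1, {
    x <- stats::runif(1000, 0.001, 0.999)
    y <- stats::rbinom(1000, 1, 0.5)
  })
  plain <- -(y * log(x) + (1 - y) * log(1 - x))
  expect_lt(max(abs(weighted_bce(x, y, 1, reduce = "none") - plain)), 1e-10)
})

test_that("checkpoint selection matches its definition and a brute-force scan", {
  expect_equal(select_checkpoint(c(1.0, 0.8, 0.9, 0.7), "first_local_min"), 2)
  expect_equal(select_checkpoint(c(1.0, 0.8, 0.9, 0.7), "global_min"), 4)
  expect_equal(select_checkpoint(c(1.0, 0.9, 0.8, 0.7), "first_local_min"), 4)
  expect_equal(select_checkpoint(c(0.5, 0.9, 0.8), "first_local_min"), 1)
  expect_equal(select_checkpoint(c(0.7, 0.7, 0.9), "global_min"), 1)
  brute <- function(v, strategy) {
    if (strategy == "global_min") return(which(v == min(v))[1])
    cand <- Filter(function(i) (i == 1 || v[i] <= v[i - 1]) &&
                     (i < length(v) && v[i] < v[i + 1]), seq_along(v))
    if (length(cand)) cand[1] else which(v == min(v))[1]
  }
  for (s in 1:100) {
    v <- withr::with_seed(s, round(stats::runif(sample(3:15, 1)), 2))
    for (st in c("first_local_min", "global_min"))
      expect_equal(select_checkpoint(v, st), brute(v, st))
  }
})

test_that("classifier outputs, freezing and seeding honour their contracts", {
  cfg <- quick_cfg(size = 32, seed = 3)
  m1 <- build_classifier(cfg)
  m2 <- build_classifier(cfg)
  expect_identical(epihfo:::get_model_state(m1), epihfo:::get_model_state(m2))
  x <- withr::with_seed(4, array(stats::rnorm(32 * 32 * 3 * 4), dim = c(32, 32, 3, 4)))
  p <- predict(m1, x)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p, predict(m1, x, batch_size = 1), tolerance = 1e-6)
  expect_error(predict(m1, x[1:16, 1:16, , , drop = FALSE]), "shape")
  expect_error(build_classifier(quick_cfg(size = 30)), "incompatible")

  # a training step with a frozen backbone leaves backbone parameters
  # bit-identical while head parameters move
  ts <- toy_stacks(10, size = 32, seed = 5)
  tr <- train_classifier(ts$x, ts$y, quick_cfg(size = 32, epochs = 1, seed = 6),
                         ts$x, ts$y, model = m1, frozen_backbone = TRUE)
  st0 <- epihfo:::get_model_state(m1)
  st1 <- epihfo:::get_model_state(tr$model)
  expect_identical(st1$bb_params, st0$bb_params)
  expect_false(identical(st1$head_params, st0$head_params))
})

test_that("training learns a separable toy and is reproducible", {
  ts <- toy_stacks(40, size = 32, seed = 7)
  vs <- toy_stacks(10, size = 32, seed = 8)
  cfg <- quick_cfg(size = 32, epochs = 6, seed = 9)
  tr <- train_classifier(ts$x, ts$y, cfg, vs$x, vs$y)
  expect_lt(tr$record$train_loss[tr$record$selected_epoch],
            tr$record$train_loss[1])
  expect_equal(tr$record$selected_epoch,
               select_checkpoint(tr$record$val_loss, cfg$checkpoint_strategy))
  tr2 <- train_classifier(ts$x, ts$y, cfg, vs$x, vs$y)
  expect_identical(tr$record$train_loss, tr2$record$train_loss)
  expect_identical(tr$record$val_loss, tr2$record$val_loss)
  expect_identical(predict(tr$model, vs$x), predict(tr2$model, vs$x))
  # all-ones weights reproduce the unweighted trajectory
  tr3 <- train_classifier(ts$x, ts$y, cfg, vs$x, vs$y,
                          w_train = rep(1, length(ts$y)),
                          w_val = rep(1, length(vs$y)))
  expect_lt(max(abs(tr3$record$train_loss - tr$record$train_loss)), 1e-7)
  expect_warning(
    train_classifier(ts$x[, , , 1:5, drop = FALSE], rep(0, 5),
                     quick_cfg(size = 32, epochs = 1, seed = 1),
                     vs$x[, , , 1:2, drop = FALSE], vs$y[1:2]),
    "single class")
})

test_that("cross-validation builds the prescribed folds", {
  ts <- toy_stacks(25, size = 32, seed = 10)
  pats <- rep(paste0("pt", 1:5), 10)
  cfg <- quick_cfg(size = 32, epochs = 2, seed = 11)
  cv <- suppressWarnings(
    cross_validate(ts$x, ts$y, pats, scheme = "patient_wise", config = cfg))
  expect_length(cv$folds, 5)
  expect_setequal(sapply(cv$folds, `[[`, "fold"), paste0("pt", 1:5))
  expect_named(cv$mean, c("accuracy", "recall", "precision", "f1"))
  cv2 <- suppressWarnings(
    cross_validate(ts$x, ts$y, pats, scheme = "kfold", k = 5, config = cfg))
  expect_length(cv2$folds, 5)
  # test folds partition the data and are reproducible per seed
  expect_setequal(unlist(lapply(cv2$folds, `[[`, "test_idx")), seq_len(50))
  cv3 <- suppressWarnings(
    cross_validate(ts$x, ts$y, pats, scheme = "kfold", k = 5, config = cfg))
  expect_identical(lapply(cv2$folds, `[[`, "test_idx"),
                   lapply(cv3$folds, `[[`, "test_idx"))
})
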