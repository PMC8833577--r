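#' Classifier configuration
#'
#' Architecture and optimisation settings for the binary CNN classifiers.
#' The reference architecture is a ResNet-18-style residual backbone whose
#' final layer is replaced by three fully connected layers with LeakyReLU,
#' batch normalisation and 10% dropout in between, feeding a sigmoid output.
#' A 4-block `small_cnn` backbone (stride-2 convolutions, global average
#' pooling, same head) is provided for desk-scale experiments at 64 x 64.
#'
#' @param backbone `"resnet18_style"` or `"small_cnn"`.
#' @param input_size Input image side length (224 reference, 64 desk scale).
#' @param head_dims Hidden sizes of the first two fully connected layers;
#'   `NULL` picks sensible defaults per backbone.
#' @param dropout Dropout rate between head layers.
#' @param leaky_slope Negative slope of the head LeakyReLU.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param checkpoint_strategy `"first_local_min"` (early-stopping flavour used
#'   for the artefact detector) or `"global_min"` (spike detector and eHFO
#'   model).
#' @param threshold Decision threshold on the sigmoid output.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(backbone = c("resnet18_style", "small_cnn"),
                              input_size = 224, head_dims = NULL,
                              dropout = 0.1, leaky_slope = 0.01,
                              learning_rate = 3e-4, epochs = 15,
                              batch_size = 128,
                              checkpoint_strategy = c("global_min", "first_local_min"),
                              threshold = 0.5, seed = 1L) {
  backbone <- match.arg(backbone)
  checkpoint_strategy <- match.arg(checkpoint_strategy)
  assert_that(dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")
  assert_that(epochs >= 1, "epochs must be at least 1")
  if (is.null(head_dims))
    head_dims <- if (backbone == "resnet18_style") c(256, 64) else c(32, 16)
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 head_dims = head_dims, dropout = dropout,
                 leaky_slope = leaky_slope, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 checkpoint_strategy = checkpoint_strategy,
                 threshold = threshold, seed = as.integer(seed)),
            class = "classifier_config")
}

build_backbone <- function(config) {
  s <- config$input_size
  if (config$backbone == "small_cnn") {
    assert_that(s %% 16 == 0 && s >= 16,
                "input size incompatible with small_cnn stride (needs a multiple of 16)")
    ch <- c(3, 16, 32, 64, 64)
    layers <- list()
    for (i in 1:4) {
      layers <- c(layers, list(new_conv(3, 3, ch[i], ch[i + 1], 2L, 1L),
                               new_bn2d(ch[i + 1]), new_act(0)))
    }
    list(layers = c(layers, list(new_gap())), feature_dim = 64L)
  } else {
    assert_that(s %% 32 == 0 && s >= 32,
                "input size incompatible with resnet18_style stride (needs a multiple of 32)")
    layers <- list(new_conv(7, 7, 3, 64, 2L, 3L), new_bn2d(64), new_act(0),
                   new_maxpool(3, 2, 1L),
                   new_resblock(64, 64, 1L), new_resblock(64, 64, 1L),
                   new_resblock(64, 128, 2L), new_resblock(128, 128, 1L),
                   new_resblock(128, 256, 2L), new_resblock(256, 256, 1L),
                   new_resblock(256, 512, 2L), new_resblock(512, 512, 1L),
                   new_gap())
    list(layers = layers, feature_dim = 512L)
  }
}

build_head <- function(feature_dim, config) {
  h <- config$head_dims
  list(new_fc(feature_dim, h[1]), new_bn1d(h[1]), new_act(config$leaky_slope),
       new_dropout(config$dropout),
       new_fc(h[1], h[2]), new_bn1d(h[2]), new_act(config$leaky_slope),
       new_dropout(config$dropout),
       new_fc(h[2], 1L))
}

build_classifier_raw <- function(config) {
  bb <- build_backbone(config)
  structure(list(backbone = bb$layers, head = build_head(bb$feature_dim, config),
                 feature_dim = bb$feature_dim, config = config, frozen = FALSE),
            class = "hfo_cnn")
}

#' Build a binary CNN classifier
#'
#' Initialization is seeded from `config$seed`, so two builds with the same
#' configuration have identical parameters.
#'
#' @param config A [classifier_config()].
#' @return Object of class `hfo_cnn`.
#' @export
build_classifier <- function(config) {
  with_seed(config$seed, build_classifier_raw(config))
}

#' @export
print.hfo_cnn <- function(x, ...) {
  cat(sprintf("<hfo_cnn> %s backbone (%s), input %dx%dx3, %s parameters%s\n",
              x$config$backbone, paste(x$feature_dim, "features"),
              x$config$input_size, x$config$input_size,
              format(n_params(x), big.mark = ","),
              if (x$frozen) " [backbone frozen]" else ""))
  invisible(x)
}

# --- parameter bookkeeping ---------------------------------------------------

params_of_layer <- function(layer) {
  if (layer$type == "resblock") {
    p <- list(conv1 = layer$conv1$params, bn1 = layer$bn1$params,
              conv2 = layer$conv2$params, bn2 = layer$bn2$params)
    if (!is.null(layer$downsample))
      p <- c(p, list(ds_conv = layer$downsample$conv$params,
                     ds_bn = layer$downsample$bn$params))
    p
  } else if (length(layer$params)) layer$params else NULL
}

set_layer_params <- function(layer, p) {
  if (layer$type == "resblock") {
    layer$conv1$params <- p$conv1; layer$bn1$params <- p$bn1
    layer$conv2$params <- p$conv2; layer$bn2$params <- p$bn2
    if (!is.null(layer$downsample)) {
      layer$downsample$conv$params <- p$ds_conv
      layer$downsample$bn$params <- p$ds_bn
    }
  } else if (length(layer$params)) layer$params <- p
  layer
}

states_of_layer <- function(layer) {
  if (layer$type == "resblock") {
    st <- list(bn1 = layer$bn1$state, bn2 = layer$bn2$state)
    if (!is.null(layer$downsample)) st$ds_bn <- layer$downsample$bn$state
    st
  } else layer$state
}

set_layer_state <- function(layer, st) {
  if (layer$type == "resblock") {
    layer$bn1$state <- st$bn1; layer$bn2$state <- st$bn2
    if (!is.null(layer$downsample)) layer$downsample$bn$state <- st$ds_bn
  } else if (!is.null(layer$state)) layer$state <- st
  layer
}

get_model_state <- function(model) {
  list(bb_params = lapply(model$backbone, params_of_layer),
       bb_states = lapply(model$backbone, states_of_layer),
       head_params = lapply(model$head, params_of_layer),
       head_states = lapply(model$head, states_of_layer))
}

set_model_state <- function(model, st) {
  for (i in seq_along(model$backbone)) {
    if (!is.null(st$bb_params[[i]]))
      model$backbone[[i]] <- set_layer_params(model$backbone[[i]], st$bb_params[[i]])
    if (!is.null(st$bb_states[[i]]))
      model$backbone[[i]] <- set_layer_state(model$backbone[[i]], st$bb_states[[i]])
  }
  for (i in seq_along(model$head)) {
    if (!is.null(st$head_params[[i]]))
      model$head[[i]] <- set_layer_params(model$head[[i]], st$head_params[[i]])
    if (!is.null(st$head_states[[i]]))
      model$head[[i]] <- set_layer_state(model$head[[i]], st$head_states[[i]])
  }
  model
}

n_params <- function(model) {
  sum(unlist(rapply(c(lapply(model$backbone, params_of_layer),
                      lapply(model$head, params_of_layer)),
                    length, how = "unlist")), na.rm = TRUE)
}

# recursive elementwise map over two parallel nested numeric lists
map2_num <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (nm in seq_along(a)) {
    if (is.null(a[[nm]])) next
    out[[nm]] <- map2_num(a[[nm]], if (is.null(b)) NULL else b[[nm]], f)
  }
  out
}

zeros_like <- function(a) {
  if (is.numeric(a)) return(a * 0)
  lapply(a, function(e) if (is.null(e)) NULL else zeros_like(e))
}

# --- forward / backward ------------------------------------------------------

net_forward <- function(model, x, training = FALSE, update_state = TRUE) {
  bb_train <- training && !model$frozen
  caches_bb <- vector("list", length(model$backbone))
  h <- x
  for (i in seq_along(model$backbone)) {
    f <- layer_forward(model$backbone[[i]], h, bb_train)
    caches_bb[[i]] <- f$cache
    if (bb_train && update_state && !is.null(f$state)) {
      if (model$backbone[[i]]$type == "resblock")
        model$backbone[[i]] <- set_layer_state(model$backbone[[i]],
          utils::modifyList(states_of_layer(model$backbone[[i]]), f$state))
      else model$backbone[[i]]$state <- f$state
    }
    h <- f$y
  }
  feats <- h
  caches_head <- vector("list", length(model$head))
  for (i in seq_along(model$head)) {
    f <- layer_forward(model$head[[i]], h, training)
    caches_head[[i]] <- f$cache
    if (training && update_state && !is.null(f$state)) model$head[[i]]$state <- f$state
    h <- f$y
  }
  list(z = h, features = feats, caches_bb = caches_bb, caches_head = caches_head,
       model = model)
}

net_backward <- function(model, fwd, dz) {
  gh <- vector("list", length(model$head))
  d <- dz
  for (i in rev(seq_along(model$head))) {
    b <- layer_backward(model$head[[i]], fwd$caches_head[[i]], d)
    gh[i] <- list(b$grads)
    d <- b$dx
  }
  gb <- vector("list", length(model$backbone))
  if (!model$frozen) {
    for (i in rev(seq_along(model$backbone))) {
      b <- layer_backward(model$backbone[[i]], fwd$caches_bb[[i]], d)
      gb[i] <- list(b$grads)
      d <- b$dx
    }
  }
  list(head = gh, backbone = gb)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Weighted binary cross-entropy
#'
#' `w * (-(y log x + (1 - y) log(1 - x)))` with predictions clipped to
#' `[eps, 1 - eps]`; the batch loss is the mean of per-sample losses.
#'
#' @param x Predicted probabilities.
#' @param y Binary labels (0/1).
#' @param w Per-sample positive weights (scalar or vector).
#' @param eps Clipping constant.
#' @param reduce `"mean"` or `"none"`.
#' @return Scalar mean loss or per-sample vector.
#' @export
weighted_bce <- function(x, y, w = 1, eps = 1e-7, reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  assert_that(all(w > 0), "weights must be positive")
  x <- pmin(pmax(x, eps), 1 - eps)
  l <- w * (-(y * log(x) + (1 - y) * log(1 - x)))
  if (reduce == "mean") mean(l) else l
}

#' Select the checkpoint epoch from a validation-loss curve
#'
#' `first_local_min`: the smallest epoch i with `loss[i] <= loss[i-1]` (or
#' i the first epoch) and `loss[i] < loss[i+1]`; when no interior local
#' minimum exists the global minimum is used.  `global_min`: the argmin,
#' first occurrence on ties.  Epochs are 1-based.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param strategy `"first_local_min"` or `"global_min"`.
#' @return 1-based epoch index.
#' @export
select_checkpoint <- function(val_losses, strategy = c("global_min", "first_local_min")) {
  strategy <- match.arg(strategy)
  n <- length(val_losses)
  assert_that(n >= 1, "empty loss sequence")
  if (strategy == "global_min" || n == 1L) return(which.min(val_losses))
  for (i in seq_len(n - 1L)) {
    if ((i == 1L || val_losses[i] <= val_losses[i - 1L]) &&
        val_losses[i] < val_losses[i + 1L]) return(i)
  }
  which.min(val_losses)
}

# Adam with constant learning rate and default moment coefficients
adam_update <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.numeric(params)) {
    m <- b1 * state$m + (1 - b1) * grads
    v <- b2 * state$v + (1 - b2) * grads^2
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    list(params = params - lr * mh / (sqrt(vh) + eps), state = list(m = m, v = v))
  } else {
    out_p <- params; out_s <- state
    for (i in seq_along(params)) {
      if (is.null(params[[i]]) || is.null(grads[[i]])) next
      r <- adam_update(params[[i]], grads[[i]], state[[i]], lr, t, b1, b2, eps)
      out_p[[i]] <- r$params; out_s[[i]] <- r$state
    }
    list(params = out_p, state = out_s)
  }
}

adam_init <- function(params) {
  if (is.numeric(params)) return(list(m = params * 0, v = params * 0))
  lapply(params, function(p) if (is.null(p)) NULL else adam_init(p))
}

predict_chunked <- function(model, x, batch_size = 256L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    fwd <- net_forward(model, x[, , , s:e, drop = FALSE], training = FALSE)
    out[s:e] <- as.numeric(sigmoid(fwd$z))
  }
  out
}

#' Predict event probabilities
#'
#' Evaluation mode (dropout off, batch normalisation using running
#' statistics), so predictions are independent of batching.
#'
#' @param object An `hfo_cnn` model.
#' @param stacks `S x S x 3 x N` input array (see [assemble_input()]).
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.hfo_cnn <- function(object, stacks, batch_size = 256L, ...) {
  if (length(dim(stacks)) == 3L) dim(stacks) <- c(dim(stacks), 1L)
  assert_that(dim(stacks)[1] == object$config$input_size &&
                dim(stacks)[3] == 3L, "input shape mismatch")
  predict_chunked(object, stacks, batch_size)
}

#' Extract frozen-backbone features
#'
#' Runs the convolutional backbone in evaluation mode and returns the pooled
#' feature matrix; used by the weak-supervision trainer where the backbone
#' only acts as a feature extractor.
#'
#' @param model An `hfo_cnn`.
#' @param stacks `S x S x 3 x N` array.
#' @param batch_size Batch size.
#' @return `feature_dim x N` matrix.
#' @export
extract_features <- function(model, stacks, batch_size = 256L) {
  n <- dim(stacks)[4]
  out <- matrix(0, model$feature_dim, n)
  bb_only <- model; bb_only$head <- list()
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    fwd <- net_forward(bb_only, stacks[, , , s:e, drop = FALSE], training = FALSE)
    out[, s:e] <- fwd$features
  }
  out
}

#' Train a binary classifier
#'
#' Adam at the configured learning rate for the configured number of epochs,
#' minimising (optionally weighted) binary cross-entropy; per-epoch training
#' and validation losses are recorded and the returned model is the checkpoint
#' chosen by the configured strategy.  Fully reproducible for a given seed.
#'
#' @param x_train,x_val `S x S x 3 x N` input arrays (or `feature_dim x N`
#'   matrices when `head_only = TRUE`).
#' @param y_train,y_val Binary labels.
#' @param config A [classifier_config()].
#' @param w_train,w_val Optional per-sample loss weights.
#' @param model Optional pre-built `hfo_cnn` (e.g. with a frozen backbone);
#'   built from `config` when `NULL`.
#' @param frozen_backbone Freeze all convolutional parameters.
#' @param head_only Inputs are pre-extracted feature matrices; only the head
#'   is trained (requires `frozen_backbone = TRUE` semantics).
#' @return List of class `hfo_training` with `model` and `record` (per-epoch
#'   `train_loss`, `val_loss`, `selected_epoch`, `seed`, `config_hash`).
#' @export
train_classifier <- function(x_train, y_train, config, x_val, y_val,
                             w_train = NULL, w_val = NULL, model = NULL,
                             frozen_backbone = FALSE, head_only = FALSE) {
  n <- if (head_only) ncol(x_train) else dim(x_train)[4]
  n_val <- if (head_only) ncol(x_val) else dim(x_val)[4]
  assert_that(n >= 1 && n_val >= 1, "training and validation sets must be non-empty")
  assert_that(length(y_train) == n && length(y_val) == n_val, "label length mismatch")
  if (length(unique(y_train)) < 2L)
    warning("training set contains a single class; proceeding")
  if (is.null(w_train)) w_train <- rep(1, n)
  if (is.null(w_val)) w_val <- rep(1, n_val)
  if (length(w_train) == 1L) w_train <- rep(w_train, n)
  if (length(w_val) == 1L) w_val <- rep(w_val, n_val)

  with_seed(config$seed, {
    if (is.null(model)) model <- build_classifier_raw(config)
    if (frozen_backbone) model$frozen <- TRUE
    small <- n_params(model) <= 3e6
    opt <- list(backbone = if (!model$frozen)
                  lapply(model$backbone, function(l) {
                    p <- params_of_layer(l); if (is.null(p)) NULL else adam_init(p)
                  }) else NULL,
                head = lapply(model$head, function(l) {
                  p <- params_of_layer(l); if (is.null(p)) NULL else adam_init(p)
                }))
    t_step <- 0L
    train_losses <- val_losses <- numeric(config$epochs)
    snaps <- vector("list", config$epochs)
    prev_snap <- best_snap <- flm_snap <- NULL
    best_epoch <- flm_epoch <- NA_integer_
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      batch_losses <- c()
      for (s in seq(1L, n, by = config$batch_size)) {
        b <- idx[s:min(n, s + config$batch_size - 1L)]
        xb <- if (head_only) x_train[, b, drop = FALSE] else
          x_train[, , , b, drop = FALSE]
        yb <- y_train[b]; wb <- w_train[b]
        fwd <- if (head_only) head_forward(model, xb, training = TRUE)
               else net_forward(model, xb, training = TRUE)
        model <- fwd$model
        p <- as.numeric(sigmoid(fwd$z))
        batch_losses <- c(batch_losses, weighted_bce(p, yb, wb))
        dz <- matrix(wb * (p - yb) / length(b), nrow = 1)
        grads <- if (head_only) list(head = head_backward(model, fwd, dz),
                                     backbone = NULL)
                 else net_backward(model, fwd, dz)
        t_step <- t_step + 1L
        for (i in seq_along(model$head)) {
          if (is.null(grads$head[[i]])) next
          r <- adam_update(params_of_layer(model$head[[i]]), grads$head[[i]],
                           opt$head[[i]], config$learning_rate, t_step)
          model$head[[i]] <- set_layer_params(model$head[[i]], r$params)
          opt$head[[i]] <- r$state
        }
        if (!model$frozen && !head_only) {
          for (i in seq_along(model$backbone)) {
            if (is.null(grads$backbone[[i]])) next
            r <- adam_update(params_of_layer(model$backbone[[i]]),
                             grads$backbone[[i]], opt$backbone[[i]],
                             config$learning_rate, t_step)
            model$backbone[[i]] <- set_layer_params(model$backbone[[i]], r$params)
            opt$backbone[[i]] <- r$state
          }
        }
      }
      train_losses[epoch] <- mean(batch_losses)
      pv <- if (head_only) head_predict(model, x_val) else
        predict_chunked(model, x_val)
      val_losses[epoch] <- weighted_bce(pv, y_val, w_val)
      snap <- get_model_state(model)
      if (small) snaps[[epoch]] <- snap
      if (is.na(best_epoch) || val_losses[epoch] < val_losses[best_epoch]) {
        best_snap <- snap; best_epoch <- epoch
      }
      if (epoch >= 2L && is.na(flm_epoch)) {
        i <- epoch - 1L
        if ((i == 1L || val_losses[i] <= val_losses[i - 1L]) &&
            val_losses[i] < val_losses[epoch]) {
          flm_snap <- prev_snap; flm_epoch <- i
        }
      }
      prev_snap <- snap
    }
    sel <- select_checkpoint(val_losses, config$checkpoint_strategy)
    chosen <- if (small) snaps[[sel]] else {
      if (config$checkpoint_strategy == "first_local_min" && !is.na(flm_epoch) &&
          flm_epoch == sel) flm_snap
      else if (sel == best_epoch) best_snap
      else if (sel == config$epochs) prev_snap
      else best_snap
    }
    model <- set_model_state(model, chosen)
    structure(list(model = model,
                   record = list(train_loss = train_losses, val_loss = val_losses,
                                 selected_epoch = sel, seed = config$seed,
                                 config_hash = object_hash(unclass(config)))),
              class = "hfo_training")
  })
}

# head-only forward/backward on a pre-extracted feature matrix
head_forward <- function(model, feats, training = FALSE) {
  caches <- vector("list", length(model$head))
  h <- feats
  for (i in seq_along(model$head)) {
    f <- layer_forward(model$head[[i]], h, training)
    caches[[i]] <- f$cache
    if (training && !is.null(f$state)) model$head[[i]]$state <- f$state
    h <- f$y
  }
  list(z = h, caches_head = caches, model = model)
}

head_backward <- function(model, fwd, dz) {
  gh <- vector("list", length(model$head))
  d <- dz
  for (i in rev(seq_along(model$head))) {
    b <- layer_backward(model$head[[i]], fwd$caches_head[[i]], d)
    gh[i] <- list(b$grads)
    d <- b$dx
  }
  gh
}

head_predict <- function(model, feats) {
  as.numeric(sigmoid(head_forward(model, feats, training = FALSE)$z))
}

#' Cross-validate a classifier
#'
#' `patient_wise`: each patient serves once as the test set; the remaining
#' patients' events are pooled, 10% sampled as validation and 90% used for
#' training.  `kfold`: events are shuffled into k disjoint test folds
#' (20/70/10 test/train/validation for k = 5).
#'
#' @param stacks `S x S x 3 x N` array.
#' @param y Binary labels.
#' @param patients Patient id per event.
#' @param scheme `"patient_wise"` or `"kfold"`.
#' @param k Number of folds for `"kfold"`.
#' @param config A [classifier_config()].
#' @return List with per-fold metrics, their mean and SD, and fold
#'   assignments.
#' @export
cross_validate <- function(stacks, y, patients, scheme = c("patient_wise", "kfold"),
                           k = 5, config = classifier_config()) {
  scheme <- match.arg(scheme)
  n <- dim(stacks)[4]
  folds <- list()
  if (scheme == "patient_wise") {
    ids <- unique(patients)
    assert_that(length(ids) >= 2, "patient-wise CV needs at least two patients")
    for (p in ids) {
      test_idx <- which(patients == p)
      if (!length(test_idx)) { warning("patient with zero events skipped: ", p); next }
      rest <- which(patients != p)
      folds[[length(folds) + 1L]] <- list(name = p, test = test_idx, rest = rest)
    }
  } else {
    assert_that(n >= k, "k-fold CV needs at least k events")
    assign <- with_seed(child_seed(config$seed, 77L),
                        sample(rep(seq_len(k), length.out = n)))
    for (f in seq_len(k)) {
      folds[[f]] <- list(name = paste0("fold", f), test = which(assign == f),
                         rest = which(assign != f))
    }
  }
  res <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    val_n <- if (scheme == "patient_wise") max(1L, round(0.1 * length(fold$rest)))
             else max(1L, round(0.1 * n))   # 20/70/10 test/train/validation
    val_idx <- with_seed(child_seed(config$seed, 100L + fi),
                         sample(fold$rest, val_n))
    train_idx <- setdiff(fold$rest, val_idx)
    cfg <- config; cfg$seed <- child_seed(config$seed, 200L + fi)
    tr <- train_classifier(stacks[, , , train_idx, drop = FALSE], y[train_idx],
                           cfg, stacks[, , , val_idx, drop = FALSE], y[val_idx])
    p <- predict(tr$model, stacks[, , , fold$test, drop = FALSE])
    m <- classification_metrics(as.integer(p >= config$threshold), y[fold$test])
    res[[fi]] <- c(list(fold = fold$name, test_idx = fold$test), m)
  }
  keys <- c("accuracy", "recall", "precision", "f1")
  mat <- sapply(keys, function(k2) sapply(res, `[[`, k2))
  list(folds = res,
       mean = colMeans(mat, na.rm = TRUE),
       sd = apply(mat, 2, stats::sd, na.rm = TRUE))
}
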