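#' Assign resection/outcome-derived weak labels
#'
#' Events from resected channels are labelled 1, events from preserved
#' channels 0.  Loss weights: w = 1 for preserved-channel events and for
#' resected SOZ-channel events; w = 0.5 for resected non-SOZ-channel events
#' (anatomical-margin resections are the least trustworthy positives).
#' Events of patients who are not seizure-free are flagged ineligible for
#' training (the all-epileptogenic-tissue-resected assumption fails there).
#'
#' @param events Data frame with `patient` and `channel`.
#' @param channel_meta Data frame with `patient`, `channel`, `resected`, `soz`.
#' @param outcomes Data frame with `patient`, `seizure_free` (0/1).
#' @param w_nonsoz Weight for resected non-SOZ events (default 0.5).
#' @return `events` with added columns `y`, `w`, `eligible_for_training`.
#' @export
assign_weak_labels <- function(events, channel_meta, outcomes, w_nonsoz = 0.5) {
  key <- paste(events$patient, events$channel)
  mkey <- paste(channel_meta$patient, channel_meta$channel)
  m <- match(key, mkey)
  assert_that(!anyNA(m), "event channel missing from channel metadata",
              class = "epihfo_label_error")
  resected <- channel_meta$resected[m] > 0
  soz <- channel_meta$soz[m] > 0
  om <- match(events$patient, outcomes$patient)
  assert_that(!anyNA(om), "event patient missing from outcomes",
              class = "epihfo_label_error")
  out <- events
  out$y <- as.integer(resected)
  out$w <- ifelse(resected & !soz, w_nonsoz, 1)
  out$eligible_for_training <- outcomes$seizure_free[om] > 0
  out
}

#' Filter probable artefacts with a trained artefact detector
#'
#' Keeps events whose real-HFO probability is at or above the threshold.
#'
#' @param events Event data frame.
#' @param probabilities Real-HFO probability per event (from the artefact
#'   detector, where 1 = real HFO).
#' @param threshold Keep threshold.
#' @return Subset of `events` with a `real_hfo_prob` provenance column.
#' @export
filter_artifacts <- function(events, probabilities, threshold = 0.5) {
  assert_that(length(probabilities) == nrow(events),
              "one probability per event required")
  out <- events
  out$real_hfo_prob <- probabilities
  out[probabilities >= threshold, , drop = FALSE]
}

#' Cap the number of events contributed per patient
#'
#' Patients with at most `cap` events keep all of them; others contribute
#' exactly `cap` events sampled uniformly without replacement (deterministic
#' per seed).
#'
#' @param events Event data frame with a `patient` column.
#' @param cap Per-patient cap (default 2500, the median per-patient count in
#'   the reference cohort).
#' @param seed Integer seed.
#' @return Row indices into `events` of the retained subset, sorted.
#' @export
cap_sample_per_patient <- function(events, cap = 2500, seed = 1L) {
  assert_that(cap >= 1, "cap must be at least 1")
  with_seed(seed, {
    keep <- unlist(lapply(unique(events$patient), function(p) {
      idx <- which(events$patient == p)
      if (length(idx) <= cap) idx else sample(idx, cap)
    }))
    sort(keep)
  })
}

#' Patient-specific training pool
#'
#' For a seizure-free target patient the training pool is all *other*
#' seizure-free patients; for a non-seizure-free target it is all
#' seizure-free patients.  The target's own events are never eligible.
#'
#' @param events Weak-labelled event data frame (see [assign_weak_labels()]).
#' @param outcomes Outcome table with `patient`, `seizure_free`.
#' @param target_patient Patient id the model is being built for.
#' @return Logical vector over rows of `events`: TRUE = in the training pool.
#' @export
build_patient_specific_split <- function(events, outcomes, target_patient) {
  assert_that(target_patient %in% outcomes$patient, "target patient not in cohort")
  free <- outcomes$patient[outcomes$seizure_free > 0]
  pool <- setdiff(free, target_patient)
  assert_that(length(pool) >= 1, "no seizure-free patients available for training")
  sel <- events$patient %in% pool & events$eligible_for_training
  # leakage guard: the target must never contribute training events
  stopifnot(!any(events$patient[sel] == target_patient))
  sel
}

#' Train the weakly supervised eHFO model
#'
#' Same setup as the spike detector except that the convolutional backbone is
#' initialized from the trained spike detector and frozen, acting purely as a
#' feature extractor (run in inference mode); the three-layer head is trained
#' from scratch with the weighted binary cross-entropy loss and the
#' `global_min` checkpoint rule.  Because the backbone is frozen, features are
#' extracted once and the head is optimised on them, which is mathematically
#' identical to backpropagating through the frozen stack.
#'
#' @param stacks `S x S x 3 x N` spike-task input array for the training pool.
#' @param labels Weak labels y (0/1).
#' @param weights Loss weights w.
#' @param spike_model Trained spike-detector `hfo_cnn` providing the frozen
#'   backbone.
#' @param config [classifier_config()]; `checkpoint_strategy` is forced to
#'   `"global_min"`.
#' @param val_fraction Fraction of the pool held out as validation.
#' @param features Optional pre-extracted `feature_dim x N` matrix (skips the
#'   backbone pass).
#' @return List of class `dlatrev_model` with the `hfo_cnn` model (frozen
#'   backbone + trained head) and the training record.
#' @export
train_dlatrev <- function(stacks, labels, weights, spike_model, config,
                          val_fraction = 0.1, features = NULL) {
  n <- length(labels)
  assert_that(n >= 2, "no eligible events to train on")
  config$checkpoint_strategy <- "global_min"
  config$input_size <- spike_model$config$input_size
  if (is.null(features)) features <- extract_features(spike_model, stacks)
  val_idx <- with_seed(child_seed(config$seed, 31L),
                       sample.int(n, max(1L, round(val_fraction * n))))
  tr_idx <- setdiff(seq_len(n), val_idx)
  model <- spike_model
  model$frozen <- TRUE
  model$head <- with_seed(config$seed, build_head(model$feature_dim, config))
  tr <- train_classifier(features[, tr_idx, drop = FALSE], labels[tr_idx], config,
                         features[, val_idx, drop = FALSE], labels[val_idx],
                         w_train = weights[tr_idx], w_val = weights[val_idx],
                         model = model, frozen_backbone = TRUE, head_only = TRUE)
  structure(list(model = tr$model, record = tr$record), class = "dlatrev_model")
}

#' Classify events as eHFO / non-eHFO with a trained DLATREV model
#'
#' @param dlatrev A `dlatrev_model` (or bare `hfo_cnn` with frozen backbone).
#' @param stacks Spike-task input array for the events to classify.
#' @param threshold eHFO decision threshold.
#' @param features Optional pre-extracted feature matrix.
#' @return Data frame with `probability` and `class` (`"eHFO"`/`"non-eHFO"`).
#' @export
discover_ehfos <- function(dlatrev, stacks = NULL, threshold = 0.5,
                           features = NULL) {
  model <- if (inherits(dlatrev, "dlatrev_model")) dlatrev$model else dlatrev
  assert_that(inherits(model, "hfo_cnn"), "a trained model is required")
  if (is.null(features)) {
    assert_that(!is.null(stacks), "stacks or features must be supplied")
    features <- extract_features(model, stacks)
  }
  p <- head_predict(model, features)
  data.frame(probability = p,
             class = ifelse(p >= threshold, "eHFO", "non-eHFO"))
}
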