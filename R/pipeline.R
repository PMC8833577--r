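#' Run the end-to-end synthetic-cohort pipeline
#'
#' Orchestrates simulate -> detect -> encode -> train (artefact and spike
#' detectors) -> weakly supervised eHFO discovery -> evaluate, writing stage
#' outputs and a run manifest to `out_dir`.  Stages run in dependency order;
#' missing upstream artifacts raise stage-attributed errors.
#'
#' @param config Either a list or a YAML file path.  Recognised sections:
#'   `sim` (arguments to [sim_config()]), `detection` (arguments to
#'   [detection_params()]), `model` (arguments to [classifier_config()]),
#'   `stages` (character vector among `simulate`, `detect`, `encode`,
#'   `train`, `dlatrev`, `evaluate`), `image_size`, `targets` (patients to
#'   build eHFO models for; default all resected patients), `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, a manifest list (config hash, seeds, per-stage timing,
#'   output digests) of class `hfo_manifest`; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("hfo_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "detect", "encode", "train",
                                 "dlatrev", "evaluate")
  seed <- config$seed %||% 1L
  size <- config$image_size %||% 64L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = object_hash(config), seed = seed,
                   stages = list(), outputs = list())
  state <- new.env(parent = emptyenv())
  tic <- function() proc.time()[["elapsed"]]
  record <- function(name, t0, files = character()) {
    manifest$stages[[name]] <<- list(seconds = round(tic() - t0, 2))
    for (f in files) manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
  }
  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop_epihfo(sprintf("stage '%s' requires missing upstream artifact '%s'",
                          stage, what), "epihfo_dependency_error")
    state[[what]]
  }

  if ("simulate" %in% stages) {
    t0 <- tic()
    sc <- do.call(sim_config, utils::modifyList(config$sim %||% list(),
                                                list(seed = seed)))
    state$cohort <- generate_cohort(sc)
    write_cohort(state$cohort, file.path(out_dir, "cohort"))
    record("simulate", t0, file.path(out_dir, "cohort",
                                     c("channels.csv", "outcomes.csv", "ground_truth.csv")))
  }
  if ("detect" %in% stages) {
    t0 <- tic()
    cohort <- need("cohort", "detect")
    dp <- do.call(detection_params, config$detection %||% list())
    dets <- lapply(cohort$recordings, function(rec) {
      meta <- cohort$channels[cohort$channels$patient == rec$patient_id, ]
      ste_detect(apply_average_reference(rec, meta), dp)
    })
    state$detections <- do.call(rbind, dets)
    f <- file.path(out_dir, "events.csv")
    write_event_table(state$detections, f)
    record("detect", t0, f)
  }
  if ("encode" %in% stages) {
    t0 <- tic()
    cohort <- need("cohort", "encode")
    dets <- need("detections", "encode")
    dets <- annotate_detections(dets, cohort$events, cohort$config$sampling_rate)
    keep <- vapply(seq_len(nrow(dets)), function(i) {
      rec <- cohort$recordings[[match(dets$patient[i],
                                      sapply(cohort$recordings, `[[`, "patient_id"))]]
      half <- rec$sampling_rate %/% 2
      dets$center_sample[i] - half >= 1 &&
        dets$center_sample[i] + half - 1 <= ncol(rec$signal)
    }, logical(1))
    dets <- dets[keep, , drop = FALSE]
    windows <- lapply(seq_len(nrow(dets)), function(i) {
      rec <- cohort$recordings[[match(dets$patient[i],
                                      sapply(cohort$recordings, `[[`, "patient_id"))]]
      extract_window(rec, dets[i, ])
    })
    state$events <- dets
    state$stacks_art <- encode_batch(windows, task = "artefact", size = size)
    state$stacks_spk <- encode_batch(windows, task = "spike", size = size)
    record("encode", t0)
  }
  if ("train" %in% stages) {
    t0 <- tic()
    ev <- need("events", "train")
    mk_cfg <- function(strategy, s_off) {
      do.call(classifier_config,
              utils::modifyList(list(backbone = "small_cnn", input_size = size,
                                     checkpoint_strategy = strategy,
                                     seed = child_seed(seed, s_off)),
                                config$model %||% list()))
    }
    split <- with_seed(child_seed(seed, 5L), sample.int(nrow(ev)))
    n_val <- max(1L, round(0.1 * nrow(ev)))
    vi <- split[seq_len(n_val)]; ti <- split[-seq_len(n_val)]
    y_art <- as.integer(ev$true_class %in% hfo_classes)
    state$artefact_model <- train_classifier(
      state$stacks_art[, , , ti, drop = FALSE], y_art[ti], mk_cfg("first_local_min", 6L),
      state$stacks_art[, , , vi, drop = FALSE], y_art[vi])$model
    y_spk <- as.integer(ev$true_class == "hfo_with_spike")
    real <- which(ev$true_class %in% hfo_classes)
    rti <- intersect(ti, real); rvi <- intersect(vi, real)
    state$spike_model <- train_classifier(
      state$stacks_spk[, , , rti, drop = FALSE], y_spk[rti], mk_cfg("global_min", 7L),
      state$stacks_spk[, , , rvi, drop = FALSE], y_spk[rvi])$model
    record("train", t0)
  }
  if ("dlatrev" %in% stages) {
    t0 <- tic()
    cohort <- need("cohort", "dlatrev")
    ev <- need("events", "dlatrev")
    art <- need("artefact_model", "dlatrev")
    spk <- need("spike_model", "dlatrev")
    p_real <- predict(art, state$stacks_art)
    labelled <- assign_weak_labels(ev, cohort$channels, cohort$outcomes)
    labelled$real_hfo_prob <- p_real
    feats <- extract_features(spk, state$stacks_spk)
    targets <- config$targets %||% unique(ev$patient)
    disc <- list()
    for (tp in targets) {
      pool <- build_patient_specific_split(labelled, cohort$outcomes, tp) &
        labelled$real_hfo_prob >= 0.5
      idx <- which(pool)
      idx <- idx[cap_sample_per_patient(labelled[idx, ], cap = config$cap %||% 2500,
                                        seed = child_seed(seed, 8L))]
      cfg <- do.call(classifier_config,
                     utils::modifyList(list(backbone = "small_cnn", input_size = size,
                                            seed = child_seed(seed, 9L)),
                                       config$model %||% list()))
      dm <- train_dlatrev(NULL, labelled$y[idx], labelled$w[idx], spk, cfg,
                          features = feats[, idx, drop = FALSE])
      own <- which(ev$patient == tp & labelled$real_hfo_prob >= 0.5)
      d <- discover_ehfos(dm, features = feats[, own, drop = FALSE])
      disc[[tp]] <- cbind(ev[own, c("patient", "channel", "start_sample",
                                    "end_sample")], d)
    }
    state$discoveries <- do.call(rbind, disc)
    f <- file.path(out_dir, "discoveries.csv")
    utils::write.csv(state$discoveries, f, row.names = FALSE)
    counts <- stats::aggregate(cbind(n = probability) ~ patient + channel + class,
                               data = state$discoveries, FUN = length)
    utils::write.csv(counts, file.path(out_dir, "channel_counts.csv"),
                     row.names = FALSE)
    record("dlatrev", t0, f)
  }
  if ("evaluate" %in% stages) {
    t0 <- tic()
    cohort <- need("cohort", "evaluate")
    disc <- need("discoveries", "evaluate")
    ehfo <- disc[disc$class == "eHFO", ]
    rr <- resection_ratio(ehfo, cohort$channels)
    rr$seizure_free <- cohort$outcomes$seizure_free[
      match(rr$patient, cohort$outcomes$patient)]
    res <- list(resection_ratios = rr)
    if (length(unique(rr$seizure_free)) == 2)
      res$roc <- roc_auc(rr$resection_ratio, rr$seizure_free)[c("auc", "p_value")]
    er <- event_rates(ehfo, cohort$channels,
                      minutes = cohort$config$recording_minutes)
    res$soz_rate <- mean(er$by_patient$soz_rate, na.rm = TRUE)
    res$nonsoz_rate <- mean(er$by_patient$nonsoz_rate, na.rm = TRUE)
    f <- file.path(out_dir, "evaluation.json")
    jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA, force = TRUE)
    state$evaluation <- res
    record("evaluate", t0, f)
  }
  manifest$results <- state$evaluation
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  class(manifest) <- "hfo_manifest"
  attr(manifest, "state") <- state
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Match detections to ground-truth events by overlap on the same channel,
# attaching the true class ("background" when unmatched).
annotate_detections <- function(detections, truth, fs) {
  out <- detections
  out$true_class <- "background"
  out$epileptogenic <- FALSE
  if (!nrow(truth)) return(out)
  t_start <- truth$center_sample - round(truth$duration_ms / 1000 * fs / 2)
  t_end <- truth$center_sample + round(truth$duration_ms / 1000 * fs / 2)
  for (i in seq_len(nrow(out))) {
    cand <- which(truth$patient == out$patient[i] &
                    truth$channel == out$channel[i] &
                    t_start <= out$end_sample[i] &
                    t_end >= out$start_sample[i])
    if (length(cand)) {
      j <- cand[which.min(abs(truth$center_sample[cand] - out$center_sample[i]))]
      out$true_class[i] <- truth$true_class[j]
      out$epileptogenic[i] <- truth$epileptogenic[j]
    }
  }
  out
}
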