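#' Binary classification metrics
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), recall = TP/(TP+FN), precision =
#' TP/(TP+FP), F1 = 2/(1/recall + 1/precision).  Ratios with a zero
#' denominator are reported as `NaN` with a warning.
#'
#' @param predictions Binary 0/1 predictions.
#' @param labels Binary 0/1 labels.
#' @return List with `TP`, `TN`, `FP`, `FN`, `accuracy`, `recall`,
#'   `precision`, `f1`.
#' @export
classification_metrics <- function(predictions, labels) {
  assert_that(length(predictions) == length(labels) && length(labels) > 0,
              "predictions and labels must be non-empty and equally long")
  tp <- sum(predictions == 1 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  safe_div <- function(a, b, what) {
    if (b == 0) { warning(what, " undefined (zero denominator)"); return(NaN) }
    a / b
  }
  recall <- safe_div(tp, tp + fn, "recall")
  precision <- safe_div(tp, tp + fp, "precision")
  f1 <- if (is.nan(recall) || is.nan(precision) || recall + precision == 0) {
    warning("f1 undefined"); NaN
  } else 2 / (1 / recall + 1 / precision)
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       accuracy = (tp + tn) / length(labels),
       recall = recall, precision = precision, f1 = f1)
}

#' Per-patient resection ratio
#'
#' Ratio of events on resected channels to all events, per patient, within a
#' filtered event class.  Patients with zero events of the class are excluded
#' with a warning.
#'
#' @param events Data frame with `patient` and `channel` columns (already
#'   filtered to the class of interest).
#' @param channel_meta Data frame with `patient`, `channel`, `resected`.
#' @return Data frame with `patient`, `n_events`, `n_resected`,
#'   `resection_ratio`.
#' @export
resection_ratio <- function(events, channel_meta) {
  key <- paste(events$patient, events$channel)
  mkey <- paste(channel_meta$patient, channel_meta$channel)
  m <- match(key, mkey)
  assert_that(!anyNA(m), "event channel missing from channel metadata")
  resected <- channel_meta$resected[m] > 0
  pats <- unique(channel_meta$patient)
  out <- data.frame(patient = pats,
                    n_events = sapply(pats, function(p) sum(events$patient == p)),
                    n_resected = sapply(pats, function(p)
                      sum(resected[events$patient == p])))
  drop <- out$n_events == 0
  if (any(drop)) warning("patients with zero events excluded: ",
                         paste(out$patient[drop], collapse = ", "))
  out <- out[!drop, , drop = FALSE]
  out$resection_ratio <- out$n_resected / out$n_events
  rownames(out) <- NULL
  out
}

#' Rank-based ROC curve and AUC
#'
#' AUC via the Mann-Whitney rank formulation with midrank tie correction; the
#' p-value is a one-sided Mann-Whitney test of score separation (exact
#' enumeration when both groups are small and tie-free).
#'
#' @param scores Numeric scores (larger = more likely positive).
#' @param outcomes Logical/0-1 outcomes.
#' @return List with `roc` (data frame of FPR/TPR points), `auc`, `p_value`.
#' @export
roc_auc <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  n1 <- sum(outcomes); n0 <- sum(!outcomes)
  assert_that(n1 > 0 && n0 > 0, "both outcome classes must be present")
  r <- rank(scores)
  auc <- (sum(r[outcomes]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  wt <- suppressWarnings(stats::wilcox.test(scores[outcomes], scores[!outcomes],
                                            alternative = "greater",
                                            exact = (n1 + n0) <= 20 &&
                                              !anyDuplicated(scores)))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(threshold = thr,
                    tpr = sapply(thr, function(t) mean(scores[outcomes] >= t)),
                    fpr = sapply(thr, function(t) mean(scores[!outcomes] >= t)))
  list(roc = roc, auc = auc, p_value = wt$p.value)
}

#' Logistic outcome model on resection ratio and SOZ resection status
#'
#' Two-covariate logistic regression (maximum likelihood via `glm`) of
#' seizure freedom on the eHFO resection ratio and complete SOZ resection;
#' in-sample fitted probabilities are scored with [roc_auc()].  Complete
#' separation is detected and flagged, in which case a ridge-penalized fit
#' (`glmnet`, small lambda) is reported instead.
#'
#' @param table Data frame with `seizure_free` (0/1), `resection_ratio`,
#'   `soz_completely_resected` (0/1).
#' @return List with `fit` coefficients, `fitted` probabilities, `auc`,
#'   `p_value`, `separation` flag.
#' @export
logistic_outcome_model <- function(table) {
  assert_that(all(c("seizure_free", "resection_ratio", "soz_completely_resected")
                  %in% names(table)), "missing required columns")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(seizure_free ~ resection_ratio + soz_completely_resected,
               data = table, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  fitted_p <- as.numeric(stats::fitted(fit))
  coefs <- stats::coef(fit)
  if (sep && requireNamespace("glmnet", quietly = TRUE)) {
    x <- as.matrix(table[, c("resection_ratio", "soz_completely_resected")])
    g <- suppressWarnings(glmnet::glmnet(x, table$seizure_free,
                                         family = "binomial",
                                         alpha = 0, lambda = 0.05))
    fitted_p <- as.numeric(stats::predict(g, x, type = "response"))
    coefs <- c(as.numeric(g$a0), as.numeric(g$beta))
    names(coefs) <- c("(Intercept)", "resection_ratio", "soz_completely_resected")
  }
  r <- roc_auc(fitted_p, table$seizure_free)
  list(coefficients = coefs, fitted = fitted_p, auc = r$auc,
       p_value = r$p_value, separation = sep)
}

#' Event rates per channel and SOZ vs non-SOZ comparison
#'
#' Rate = events / minutes per channel; per-patient mean rates in SOZ and
#' non-SOZ channels are compared with a two-sided paired t-test.  Patients
#' lacking SOZ or non-SOZ channels are excluded from the paired test.
#'
#' @param events Data frame with `patient`, `channel` (already filtered to the
#'   class of interest, e.g. discovered eHFOs).
#' @param channel_meta Data frame with `patient`, `channel`, `soz`.
#' @param minutes Recording minutes (scalar or per-patient named vector).
#' @return List with `rates` (per-channel data frame), `by_patient` (mean SOZ
#'   and non-SOZ rate per patient), `t_test` (paired t-test result or NULL).
#' @export
event_rates <- function(events, channel_meta, minutes) {
  assert_that(all(minutes > 0), "minutes must be positive")
  cm <- channel_meta
  key <- paste(cm$patient, cm$channel)
  cnt <- table(paste(events$patient, events$channel))
  cm$n_events <- as.integer(cnt[key]); cm$n_events[is.na(cm$n_events)] <- 0L
  mins <- if (length(minutes) == 1) rep(minutes, nrow(cm)) else
    as.numeric(minutes[cm$patient])
  cm$rate <- cm$n_events / mins
  pats <- unique(cm$patient)
  bp <- do.call(rbind, lapply(pats, function(p) {
    sub <- cm[cm$patient == p, ]
    data.frame(patient = p,
               soz_rate = if (any(sub$soz > 0)) mean(sub$rate[sub$soz > 0]) else NA,
               nonsoz_rate = if (any(sub$soz == 0)) mean(sub$rate[sub$soz == 0]) else NA)
  }))
  ok <- stats::complete.cases(bp)
  tt <- if (sum(ok) >= 2 && stats::sd(bp$soz_rate[ok] - bp$nonsoz_rate[ok]) > 0)
    stats::t.test(bp$soz_rate[ok], bp$nonsoz_rate[ok], paired = TRUE)
  else if (sum(ok) >= 2) list(statistic = c(t = 0), p.value = 1)
  else NULL
  list(rates = cm, by_patient = bp, t_test = tt)
}

#' Association between model classes and expert classes
#'
#' 2x2 cross-tabulation of model-discovered classes (eHFO / non-eHFO) against
#' expert classes (spk-HFO / non-spk-HFO) with row proportions and a Pearson
#' chi-square test (no continuity correction by default, matching large-count
#' usage).
#'
#' @param model_class Factor/character: `"eHFO"` or `"non-eHFO"` per event.
#' @param expert_class Factor/character: `"spk"` or `"non-spk"` per event.
#' @param correct Apply Yates continuity correction.
#' @return List with `counts` (2x2 matrix), `prop_spk_eHFO` (proportion of
#'   spk events classed eHFO), `prop_nonspk_non_eHFO`, `chi_square`,
#'   `p_value`, `n`.
#' @export
crosstab_association <- function(model_class, expert_class, correct = FALSE) {
  assert_that(length(model_class) == length(expert_class) && length(model_class) > 0,
              "inputs must be non-empty and equally long")
  tab <- table(factor(model_class, levels = c("eHFO", "non-eHFO")),
               factor(expert_class, levels = c("spk", "non-spk")))
  assert_that(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
              "empty margin in cross-tabulation")
  ct <- stats::chisq.test(tab, correct = correct)
  list(counts = unclass(tab),
       prop_spk_eHFO = tab["eHFO", "spk"] / sum(tab[, "spk"]),
       prop_nonspk_non_eHFO = tab["non-eHFO", "non-spk"] / sum(tab[, "non-spk"]),
       chi_square = unname(ct$statistic), p_value = ct$p.value,
       n = sum(tab))
}
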