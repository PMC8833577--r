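test_that("classification metrics match their formulas", {
  perfect <- classification_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(perfect[c("accuracy", "recall", "precision", "f1")]),
               c(accuracy = 1, recall = 1, precision = 1, f1 = 1))
  deg <- suppressWarnings(classification_metrics(rep(0, 4), c(1, 0, 1, 0)))
  expect_equal(deg$recall, 0)
  expect_true(is.nan(deg$precision))
  m <- classification_metrics(c(rep(1, 4), rep(0, 6)),
                              c(rep(1, 3), 0, 1, 1, rep(0, 4)))
  expect_equal(m$TP, 3); expect_equal(m$FP, 1)
  expect_equal(m$FN, 2); expect_equal(m$TN, 4)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / (1 / 0.6 + 1 / 0.75))
})

test_that("f1 equals 2pr/(p+r) on random confusion tables", {
  for (s in 1:20) {
    withr::with_seed(s, {
      y <- stats::rbinom(50, 1, 0.5)
      p <- stats::rbinom(50, 1, 0.5)
    })
    m <- suppressWarnings(classification_metrics(p, y))
    if (!is.nan(m$f1))
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  }
})

test_that("resection ratios follow the event counts", {
  cm <- data.frame(patient = "p1", channel = c("a", "b"), resected = c(1, 0))
  all_res <- data.frame(patient = "p1", channel = rep("a", 4))
  expect_equal(resection_ratio(all_res, cm)$resection_ratio, 1)
  none <- data.frame(patient = "p1", channel = rep("b", 4))
  expect_equal(resection_ratio(none, cm)$resection_ratio, 0)
  mix <- data.frame(patient = "p1", channel = c("a", "a", "a", "b"))
  expect_equal(resection_ratio(mix, cm)$resection_ratio, 0.75)
  # order invariance
  expect_equal(resection_ratio(mix[4:1, ], cm)$resection_ratio, 0.75)
  expect_error(resection_ratio(data.frame(patient = "p1", channel = "zz"), cm),
               "missing")
})

test_that("rank AUC matches brute-force pair counting and pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 8), rep(c(0, 1), 4))$auc, 0.5)
  withr::with_seed(70, s <- stats::rnorm(14))
  o <- rep(c(TRUE, FALSE), c(8, 6))
  pairs <- expand.grid(i = which(o), j = which(!o))
  brute <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                       ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  r <- roc_auc(s, o)
  expect_equal(r$auc, brute)
  skip_if_not_installed("pROC")
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(o, s, quiet = TRUE,
                                              direction = "<"))))
  # negation flips the AUC
  expect_equal(roc_auc(-s, o)$auc, 1 - brute)
  expect_error(roc_auc(s, rep(TRUE, 14)), "both outcome classes")
})

test_that("logistic outcome model recovers planted effects", {
  # deterministic threshold on the ratio -> AUC 1
  tab <- data.frame(resection_ratio = seq(0, 1, length.out = 14),
                    soz_completely_resected = rep(0:1, 7))
  tab$seizure_free <- as.integer(tab$resection_ratio > 0.5)
  fit <- logistic_outcome_model(tab)
  expect_equal(fit$auc, 1)
  expect_true(fit$separation)
  # null covariates -> AUC near 0.5 at large n
  withr::with_seed(71, {
    tab2 <- data.frame(resection_ratio = stats::runif(400),
                       soz_completely_resected = stats::rbinom(400, 1, 0.5),
                       seizure_free = stats::rbinom(400, 1, 0.5))
  })
  expect_lt(abs(logistic_outcome_model(tab2)$auc - 0.5), 0.1)
  # parameter recovery within 2 SE on a planted log-odds slope
  withr::with_seed(72, {
    rr <- stats::runif(500)
    soz <- stats::rbinom(500, 1, 0.5)
    eta <- -2 + 3 * rr + 1 * soz
    yy <- stats::rbinom(500, 1, 1 / (1 + exp(-eta)))
  })
  tab3 <- data.frame(resection_ratio = rr, soz_completely_resected = soz,
                     seizure_free = yy)
  fit3 <- logistic_outcome_model(tab3)
  g <- stats::glm(seizure_free ~ resection_ratio + soz_completely_resected,
                  data = tab3, family = stats::binomial())
  se <- summary(g)$coefficients["resection_ratio", "Std. Error"]
  expect_lt(abs(fit3$coefficients["resection_ratio"] - 3), 2 * se)
})

test_that("event rates and the SOZ comparison behave as specified", {
  cm <- data.frame(patient = rep(c("p1", "p2"), each = 2),
                   channel = rep(c("s", "n"), 2), soz = rep(c(1, 0), 2))
  ev <- data.frame(patient = c(rep("p1", 9), rep("p2", 9)),
                   channel = "s")
  er <- event_rates(ev, cm, minutes = 90)
  expect_equal(er$rates$rate[er$rates$channel == "s"], c(0.1, 0.1))
  # identical SOZ/non-SOZ rates -> t = 0, p = 1
  ev2 <- data.frame(patient = rep(c("p1", "p2"), each = 4),
                    channel = rep(c("s", "s", "n", "n"), 2))
  er2 <- event_rates(ev2, cm, minutes = 10)
  expect_equal(unname(er2$t_test$statistic), 0)
  expect_equal(er2$t_test$p.value, 1)
  # planted SOZ enrichment detected across patients
  hits <- 0
  for (s in 1:5) {
    cm3 <- data.frame(patient = rep(paste0("q", 1:10), each = 4),
                      channel = rep(c("s1", "s2", "n1", "n2"), 10),
                      soz = rep(c(1, 1, 0, 0), 10))
    ev3 <- withr::with_seed(80 + s, {
      n_soz <- stats::rpois(20, 9); n_non <- stats::rpois(20, 3)
      rbind(
        data.frame(patient = rep(cm3$patient[cm3$soz == 1], n_soz),
                   channel = rep(cm3$channel[cm3$soz == 1], n_soz)),
        data.frame(patient = rep(cm3$patient[cm3$soz == 0], n_non),
                   channel = rep(cm3$channel[cm3$soz == 0], n_non)))
    })
    er3 <- event_rates(ev3, cm3, minutes = 10)
    if (er3$t_test$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("crosstab association reproduces proportions and a calibrated test", {
  mc <- c(rep("eHFO", 4573), rep("non-eHFO", 1857),
          rep("eHFO", 982), rep("non-eHFO", 2739))
  ec <- c(rep("spk", 6430), rep("non-spk", 3721))
  ct <- crosstab_association(mc, ec)
  expect_equal(ct$prop_spk_eHFO, 4573 / 6430)
  expect_equal(ct$prop_nonspk_non_eHFO, 2739 / 3721)
  expect_equal(ct$n, 10151)
  expect_lt(ct$p_value, 1e-10)
  # null calibration: rejection rate at alpha = 0.05 within [0.03, 0.07]
  rej <- withr::with_seed(81, mean(replicate(200, {
    m2 <- sample(c("eHFO", "non-eHFO"), 400, replace = TRUE)
    e2 <- sample(c("spk", "non-spk"), 400, replace = TRUE)
    crosstab_association(m2, e2)$p_value < 0.05
  })))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
  expect_error(crosstab_association(rep("eHFO", 5), rep("spk", 5)), "margin")
})
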