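test_that("dataset splitting is exhaustive, disjoint and seed-reproducible", {
  recs <- tibble::tibble(id = 1:10)
  parts <- split_dataset(recs, seed = 5)
  expect_equal(sum(vapply(parts, nrow, integer(1))), 10)
  expect_setequal(unlist(lapply(parts, function(p) p$id)), 1:10)
  again <- split_dataset(recs, seed = 5)
  expect_identical(parts, again)
  expect_error(split_dataset(recs, fractions = c(0.5, 0.2, 0.2)), "sum")

  # over many seeds the training share concentrates on 0.40
  n <- 50
  shares <- vapply(1:200, function(s)
    nrow(split_dataset(tibble::tibble(id = 1:n), seed = s)$train) / n,
    numeric(1))
  se <- sqrt(0.4 * 0.6 / (200 * n))
  expect_lt(abs(mean(shares) - 0.40), 3 * se)
})

test_that("confusion matrices count exactly and decompose accuracy", {
  ident <- confusion_matrix(c("C", "P", "P"), c("C", "P", "P"))
  expect_equal(ident$accuracy, 1)
  expect_equal(ident$rate_CP + ident$rate_PC, 0)

  # 90 true-C correct, 10 true-C called P
  cm <- confusion_matrix(c(rep("C", 90), rep("P", 10)), rep("C", 100))
  expect_equal(cm$accuracy, 0.90)
  expect_equal(cm$rate_CP, 0.10)
  expect_equal(cm$accuracy + cm$rate_CP + cm$rate_PC, 1)

  withr::with_seed(17, {
    pred <- sample(c("C", "P"), 400, replace = TRUE)
    ref <- sample(c("C", "P"), 400, replace = TRUE, prob = c(0.8, 0.2))
  })
  cm2 <- confusion_matrix(pred, ref)
  expect_equal(cm2$accuracy, mean(pred == ref))
  expect_equal(cm2$accuracy + cm2$rate_CP + cm2$rate_PC, 1)
  expect_equal(sum(tidy(cm2)$n), 400)
  expect_error(confusion_matrix("C", c("C", "P")), "length")
})

test_that("diagnostic metrics use palliation as the target outcome", {
  perfect <- confusion_matrix(c(rep("C", 5), rep("P", 5)),
                              c(rep("C", 5), rep("P", 5)))
  expect_equal(diagnostic_metrics(perfect)$estimate, rep(1, 4))

  cm <- structure(list(n_CC = 97, n_CP = 3, n_PC = 16, n_PP = 84),
                  class = "trr_confusion")
  dm <- diagnostic_metrics(cm)
  expect_equal(dm$estimate[dm$metric == "sensitivity"], 0.84)
  expect_equal(dm$estimate[dm$metric == "specificity"], 0.97)

  all_c <- confusion_matrix(rep("C", 20), c(rep("C", 15), rep("P", 5)))
  dm2 <- diagnostic_metrics(all_c)
  expect_equal(dm2$estimate[dm2$metric == "sensitivity"], 0)
  expect_equal(dm2$estimate[dm2$metric == "specificity"], 1)
  # nothing called palliative: PPV undefined
  expect_true(is.na(dm2$estimate[dm2$metric == "ppv"]))
})

test_that("Wilson intervals contain the estimate and tighten with n", {
  ci_small <- wilson_ci(8, 10)
  ci_large <- wilson_ci(800, 1000)
  for (ci in list(ci_small, ci_large)) {
    expect_lte(ci$lo, ci$estimate)
    expect_gte(ci$hi, ci$estimate)
  }
  expect_lt(ci_large$hi - ci_large$lo, ci_small$hi - ci_small$lo)
  expect_gte(wilson_ci(0, 50)$lo, 0)
  expect_lte(wilson_ci(50, 50)$hi, 1)
})

audit_records <- function() {
  tibble::tibble(
    patient_id = sprintf("p%03d", 1:100),
    stratum = rep(c("a", "b"), times = c(60, 40)))
}

test_that("stratified audit sampling respects the design exactly", {
  recs <- audit_records()
  # census of a single stratum
  census <- stratified_audit_sample(recs[recs$stratum == "a", ],
                                    n_h = c(a = 60), seed = 1)
  expect_equal(nrow(census), 60)
  expect_equal(unique(census$.weight), 1)

  s <- stratified_audit_sample(recs, n_h = c(a = 6, b = 8), seed = 2)
  expect_equal(sum(s$stratum == "a"), 6)
  expect_equal(sum(s$stratum == "b"), 8)
  expect_equal(unique(s$.weight[s$stratum == "a"]), 60 / 6)
  expect_equal(unique(s$.weight[s$stratum == "b"]), 40 / 8)
  expect_identical(s, stratified_audit_sample(recs, n_h = c(a = 6, b = 8),
                                              seed = 2))
  expect_error(stratified_audit_sample(recs, n_h = c(a = 61, b = 4), seed = 1),
               "only 60")
})

test_that("expansion-weighted estimates reduce, weigh and scale correctly", {
  # single stratum, weight 1: exact reduction to the pooled metrics
  cm <- confusion_matrix(c(rep("P", 40), rep("C", 60)),
                         c(rep("P", 30), rep("C", 70)))
  one <- stratified_estimates(tibble::tibble(
    w = 1, TP = cm$n_PP, FN = cm$n_PC, FP = cm$n_CP, TN = cm$n_CC))
  pooled <- diagnostic_metrics(cm)
  for (m in pooled$metric) {
    expect_equal(one$estimate[one$metric == m],
                 pooled$estimate[pooled$metric == m])
  }

  # hand-computed weighted ratio: (10*30 + 2*20) / (10*40 + 2*40) = 340/480
  two <- stratified_estimates(tibble::tibble(
    N_h = c(900, 100), n_audit = c(90, 50),
    TP = c(30, 20), FN = c(10, 20), FP = c(5, 5), TN = c(45, 5)))
  expect_equal(two$estimate[two$metric == "sensitivity"], 340 / 480)
  expect_lte(two$lo[two$metric == "sensitivity"], 340 / 480)
  expect_gte(two$hi[two$metric == "sensitivity"], 340 / 480)

  # doubling every population size leaves all estimates unchanged
  doubled <- stratified_estimates(tibble::tibble(
    N_h = 2 * c(900, 100), n_audit = c(90, 50),
    TP = c(30, 20), FN = c(10, 20), FP = c(5, 5), TN = c(45, 5)))
  expect_equal(doubled$estimate, two$estimate)

  # equal weights coincide with pooling the strata
  eq <- stratified_estimates(tibble::tibble(
    w = c(3, 3), TP = c(12, 6), FN = c(3, 4), FP = c(2, 1), TN = c(20, 30)))
  pooled_cm <- structure(list(n_PP = 18, n_PC = 7, n_CP = 3, n_CC = 50),
                         class = "trr_confusion")
  pm <- diagnostic_metrics(pooled_cm)
  for (m in pm$metric) {
    expect_equal(eq$estimate[eq$metric == m],
                 pm$estimate[pm$metric == m])
  }
})

quality_setup <- function(flip, miss, n = 12000, seed = 90) {
  withr::with_seed(seed, {
    truth <- sample(c("C", "P"), n, replace = TRUE, prob = c(0.8, 0.2))
    u <- runif(n)
    intent <- truth
    intent[u < miss] <- NA
    do_flip <- u >= miss & u < miss + flip
    intent[do_flip] <- ifelse(truth[do_flip] == "C", "P", "C")
    tibble::tibble(patient_id = sprintf("p%05d", seq_len(n)),
                   intent_flag = intent, true_role = truth)
  })
}

test_that("a perfect classifier on noiseless data reports 100 / 0 / 0", {
  recs <- quality_setup(flip = 0, miss = 0)
  pred <- recs$true_role
  recs$stratum <- agreement_stratum(pred, recs$intent_flag)
  audited <- recs
  audited$predicted <- pred
  report <- population_quality_report(recs, pred, summarise_audit(audited))
  tb <- tibble::as_tibble(report)
  get <- function(measure, method)
    tb$estimate[tb$measure == measure & tb$method == method]
  for (method in c("classification_rules", "intent_flag")) {
    expect_equal(get("pct_correct", method), 100)
    expect_equal(get("pct_incorrect", method), 0)
    expect_equal(get("pct_missing", method), 0)
  }
})

test_that("known label noise is recovered by the quality report", {
  recs <- quality_setup(flip = 0.05, miss = 0)
  pred <- recs$true_role   # classifier taken as exact; intent carries noise
  recs$stratum <- agreement_stratum(pred, recs$intent_flag)
  # full random audit: every record audited
  audited <- recs
  audited$predicted <- pred
  report <- tibble::as_tibble(
    population_quality_report(recs, pred, summarise_audit(audited)))
  est <- report$estimate[report$measure == "pct_incorrect" &
                           report$method == "intent_flag"]
  se <- 100 * sqrt(0.05 * 0.95 / nrow(recs))
  expect_lt(abs(est - 5), 3 * se)
})

test_that("auditing only disagreements overstates the success rate", {
  recs <- quality_setup(flip = 0.06, miss = 0.02, seed = 91)
  withr::with_seed(92, {
    # imperfect classifier: wrong on 8% of records
    pred <- recs$true_role
    wrong <- runif(nrow(recs)) < 0.08
    pred[wrong] <- ifelse(recs$true_role[wrong] == "C", "P", "C")
  })
  recs$stratum <- agreement_stratum(pred, recs$intent_flag)
  audited <- recs
  audited$predicted <- pred

  full <- tibble::as_tibble(population_quality_report(
    recs, pred, summarise_audit(audited)))
  disag_only <- tibble::as_tibble(population_quality_report(
    recs, pred, summarise_audit(audited[audited$stratum == "disagree", ]),
    unaudited = "assume_correct"))
  get <- function(tb, method) tb$estimate[tb$measure == "pct_correct" &
                                            tb$method == method]
  expect_gt(get(disag_only, "classification_rules"),
            get(full, "classification_rules"))
  expect_gt(get(disag_only, "intent_flag"), get(full, "intent_flag"))
})

test_that("an unaudited stratum leaves report cells unavailable by default", {
  recs <- quality_setup(flip = 0.05, miss = 0.02, seed = 93)
  pred <- recs$true_role
  recs$stratum <- agreement_stratum(pred, recs$intent_flag)
  audited <- recs[recs$stratum == "disagree", ]
  audited$predicted <- pred[recs$stratum == "disagree"]
  report <- tibble::as_tibble(
    population_quality_report(recs, pred, summarise_audit(audited)))
  expect_true(is.na(report$estimate[report$measure == "pct_correct" &
                                      report$method == "intent_flag"]))
  # observed missing share is always available
  expect_false(is.na(report$estimate[report$measure == "pct_missing" &
                                       report$method == "intent_flag"]))
})
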