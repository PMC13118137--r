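test_that("splits are stratified, disjoint, exhaustive, and seeded", {
  ids <- paste0("p", 1:10)
  labels <- rep(c(TRUE, FALSE), each = 5)
  sp <- make_splits(ids, labels, n_splits = 100, test_fraction = 0.3,
                    seed = 4)
  for (s in sp) {
    expect_length(s$test, 3)
    expect_setequal(c(s$train, s$test), ids)
    expect_length(intersect(s$train, s$test), 0)
    expect_gte(sum(s$test %in% ids[labels]), 1)
    expect_gte(sum(s$test %in% ids[!labels]), 1)
  }
  expect_identical(sp, make_splits(ids, labels, n_splits = 100,
                                   test_fraction = 0.3, seed = 4))
  expect_false(identical(sp[[1]], make_splits(ids, labels, 1, seed = 5)[[1]]))

  # stratification preserves class fractions within one participant
  ids2 <- paste0("q", 1:200)
  lab2 <- rep(c(TRUE, FALSE), c(90, 110))
  for (s in make_splits(ids2, lab2, n_splits = 20, seed = 1)) {
    expect_equal(sum(s$test %in% ids2[lab2]), 90 * 0.3, tolerance = 1)
  }
  expect_error(make_splits(ids, labels, 1, test_fraction = 0.01, seed = 1),
               "stratify")
})

test_that("confusion metrics match hand arithmetic", {
  perfect <- confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(unlist(perfect),
               c(misclassification = 0, sensitivity = 100, specificity = 100))

  # TP=3 FN=1 TN=4 FP=2
  truth <- c(rep(TRUE, 4), rep(FALSE, 6))
  pred <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, rep(FALSE, 4))
  cm <- confusion_metrics(truth, pred)
  expect_equal(cm$sensitivity, 75)
  expect_equal(cm$specificity, 400 / 6)
  expect_equal(cm$misclassification, 30)

  # no positives in truth: NaN, never silently zero
  expect_true(is.nan(confusion_metrics(rep(FALSE, 5), rep(FALSE, 5))$sensitivity))
})

test_that("ROC AUC equals the pairwise-concordance oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  set.seed(17)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    scores <- sample(round(runif(n, 0, 1), 1))   # coarse grid forces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), brute_roc_auc(scores, labels))
  }
  # a binary score's AUC is (sensitivity + specificity) / 2
  set.seed(3)
  labels <- runif(400) < 0.45
  score <- ifelse(labels, runif(400) < 0.6, runif(400) < 0.1)
  cm <- confusion_metrics(labels, score == 1)
  expect_equal(roc_auc(score, labels),
               (cm$sensitivity + cm$specificity) / 200)
  # chance level for random scores
  set.seed(19)
  expect_equal(roc_auc(runif(2000), runif(2000) < 0.5), 0.5,
               tolerance = 0.03)
  expect_error(roc_auc(1:3, rep(TRUE, 3)), "both classes")
})

test_that("ROC AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- round(rnorm(80), 1)
  labels <- runif(80) < 0.5
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE, direction = "<"))))
})

test_that("PRC AUC equals exhaustive threshold enumeration", {
  expect_equal(prc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # all-identical scores collapse to a single step at the prevalence
  expect_equal(prc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), c(3, 7))), 0.3)
  set.seed(29)
  for (i in 1:10) {
    n <- sample(6:50, 1)
    scores <- sample(round(runif(n, 0, 1), 1))
    labels <- runif(n) < 0.4
    if (!any(labels)) next
    expect_equal(prc_auc(scores, labels), brute_prc_auc(scores, labels))
  }
  expect_error(prc_auc(1:3, rep(FALSE, 3)), "positive")
})

test_that("benchmark facts are analytic across splits", {
  cl <- tiny_cohort(n = 150, seed = 61)
  bench <- model_config("benchmark")
  r <- run_experiment(cl, NULL, bench, n_splits = 30, seed = 2)
  spec <- r[r$metric == "specificity", ]
  expect_equal(spec$mean, 100)
  expect_equal(spec$ci_hi - spec$ci_lo, 0)

  r_low <- run_experiment(cl, NULL, bench, n_splits = 30, seed = 2,
                          population = "low_hba1c")
  expect_equal(r_low$mean[r_low$metric == "sensitivity"], 0)
  expect_equal(r_low$mean[r_low$metric == "specificity"], 100)
  expect_equal(r_low$mean[r_low$metric == "roc_auc"], 0)
})

test_that("the 2-step rule dominates the benchmark split by split", {
  co <- generate_cohort(generator_config(n_participants = 120, seed = 33))
  cl <- co$clinical
  mat <- build_matrix(cl, co$features, "cgm")
  truth <- setNames(cl$status == "prediabetes", cl$participant_id)
  splits <- make_splits(cl$participant_id, truth, n_splits = 20, seed = 6)
  for (s in splits) {
    tr <- match(s$train, rownames(mat$x)); te <- match(s$test, rownames(mat$x))
    fit <- fit_classifier(mat$x[tr, ], mat$y[tr], "LR")
    two <- score_two_step(fit, mat$x[te, , drop = FALSE], mat$hba1c[te])
    bench_pred <- mat$hba1c[te] >= 5.7
    sens2 <- confusion_metrics(mat$y[te], two$pred)$sensitivity
    sensb <- confusion_metrics(mat$y[te], bench_pred)$sensitivity
    spec2 <- confusion_metrics(mat$y[te], two$pred)$specificity
    expect_gte(sens2, sensb)
    expect_lte(spec2, 100)
    # forced-positive ranking: step-1 rows precede all others
    expect_gt(min(two$score[bench_pred]), max(two$score[!bench_pred]))
  }
})

test_that("across-split CI width shrinks like one over root n_splits", {
  cl <- tiny_cohort(n = 150, seed = 71)
  bench <- model_config("benchmark")
  width <- function(n_splits) {
    r <- run_experiment(cl, NULL, bench, n_splits = n_splits, seed = 8)
    s <- r[r$metric == "sensitivity", ]
    s$ci_hi - s$ci_lo
  }
  ratio <- width(100) / width(900)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 5)
})

test_that("threshold sweep reduces to run_experiment and behaves at limits", {
  cl <- tiny_cohort(n = 100, seed = 81)
  bench <- model_config("benchmark")
  sw <- suppressWarnings(
    threshold_sweep(cl, NULL, bench, thresholds = c(4.0, 5.7), n_splits = 10,
                    seed = 3)
  )
  one <- run_experiment(cl, NULL, bench, n_splits = 10, seed = 3)
  expect_equal(sw$mean[sw$threshold == 5.7], one$mean)
  # a threshold below every value makes the rule all-positive
  low <- sw[sw$threshold == 4.0, ]
  expect_equal(low$mean[low$metric == "sensitivity"], 100)
  expect_equal(low$mean[low$metric == "specificity"], 0)
  # step-1 positive counts decrease in the threshold
  counts <- sapply(c(5.5, 5.7, 5.9), function(th) sum(cl$hba1c >= th))
  expect_true(all(diff(counts) <= 0))
})

test_that("cohort summaries run the right tests per variable type", {
  cl <- tiny_cohort(n = 200, seed = 91)
  s <- summarize_cohort(cl)
  expect_setequal(s$variable, c("sex", "ethnicity", "age", "bmi", "whr",
                                "fpg", "g2h", "hba1c"))
  expect_equal(s$test[s$variable == "sex"], "pearson_chi_square")
  expect_equal(s$test[s$variable == "g2h"], "mann_whitney_u")
  # glucose channels must separate the groups; sex must not
  expect_true(all(s$significant[s$variable %in% c("fpg", "g2h", "hba1c")]))

  # identical groups: all null
  base <- cl[1:50, ]
  fake <- dplyr::bind_rows(base, base)
  fake$status <- factor(rep(c("normoglycemia", "prediabetes"), each = 50),
                        levels = levels(cl$status))
  s0 <- suppressWarnings(summarize_cohort(fake))
  expect_true(all(s0$p_value > 0.05))

  # balanced 2x2: chi-square statistic 0, p = 1
  flat <- tibble::tibble(
    sex = rep(c("male", "female"), 100),
    status = factor(rep(c("normoglycemia", "prediabetes"), each = 100),
                    levels = levels(cl$status)),
    age = 50, bmi = 25, whr = 0.85, fpg = 5, g2h = 6, hba1c = 5.5,
    ethnicity = "chinese"
  )
  s1 <- suppressWarnings(
    summarize_cohort(flat, continuous_vars = "age", categorical_vars = "sex")
  )
  expect_equal(s1$p_value[s1$variable == "sex"], 1)
})

test_that("a one-SD shift is detected by the Mann-Whitney comparison", {
  set.seed(101)
  detected <- replicate(60, {
    g1 <- rnorm(100); g2 <- rnorm(100, 1)
    wilcox.test(g1, g2)$p.value < 0.05
  })
  expect_gte(mean(detected), 0.95)
})
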