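#' Repeated random subsampling splits
#'
#' Generates `n_splits` independent train/test partitions. Stratified
#' splits (the default) preserve class fractions within one participant.
#' The sequence is a pure function of `seed`.
#'
#' @param ids Participant ids.
#' @param labels Logical class labels aligned with `ids`.
#' @param n_splits Number of splits (the headline analyses use 1000).
#' @param test_fraction Fraction of participants held out (default 0.3).
#' @param stratified Preserve class balance in each split.
#' @param seed Integer seed.
#' @return A list of `n_splits` lists with elements `train` and `test`
#'   (character id vectors); each split is disjoint and exhaustive.
#' @export
make_splits <- function(ids, labels, n_splits = 1000, test_fraction = 0.3,
                        stratified = TRUE, seed = 1) {
  stopifnot(length(ids) == length(labels), test_fraction > 0,
            test_fraction < 1)
  classes <- unique(labels)
  n_class <- vapply(classes, function(cl) sum(labels == cl), 0L)
  if (stratified) {
    # largest-remainder allocation: overall test size is round(n * fraction)
    # while class fractions are preserved within one participant
    k_total <- round(length(ids) * test_fraction)
    raw <- n_class * test_fraction
    k_class <- floor(raw)
    leftover <- k_total - sum(k_class)
    if (leftover > 0) {
      extra <- order(raw - k_class, decreasing = TRUE)[seq_len(leftover)]
      k_class[extra] <- k_class[extra] + 1
    }
    if (any(k_class < 1) || any(k_class >= n_class)) {
      stop("class too small to stratify at test fraction ", test_fraction,
           call. = FALSE)
    }
  }
  with_seed(seed, {
    lapply(seq_len(n_splits), function(i) {
      test <- if (stratified) {
        unlist(lapply(seq_along(classes), function(j) {
          sample(ids[labels == classes[j]], k_class[j])
        }), use.names = FALSE)
      } else {
        sample(ids, round(length(ids) * test_fraction))
      }
      list(train = setdiff(ids, test), test = test)
    })
  })
}

#' Confusion-matrix metrics at the hard decision threshold
#'
#' @param truth Logical true labels (TRUE = prediabetes).
#' @param pred Logical hard predictions.
#' @return A one-row tibble (`misclassification`, `sensitivity`,
#'   `specificity`, all in percent). Sensitivity is `NaN` when the truth
#'   contains no positives (and likewise specificity with no negatives),
#'   never silently zero.
#' @export
confusion_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth & pred); fn <- sum(truth & !pred)
  tn <- sum(!truth & !pred); fp <- sum(!truth & pred)
  tibble::tibble(
    misclassification = 100 * (fp + fn) / length(truth),
    sensitivity = if (tp + fn == 0) NaN else 100 * tp / (tp + fn),
    specificity = if (tn + fp == 0) NaN else 100 * tn / (tn + fp)
  )
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney estimator with tie correction (ties count one half),
#' identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Logical labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC AUC requires both classes", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated average precision: thresholds sweep the distinct
#' score values in decreasing order and each recall increment is weighted
#' by the precision at that threshold. All-identical scores give the
#' prevalence.
#'
#' @param scores Numeric scores.
#' @param labels Logical labels.
#' @return PRC AUC in `[0, 1]`.
#' @export
prc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  if (n_pos == 0) stop("PRC AUC requires positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  # evaluate only at the last index of each tie group
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cum_tp[last_of_tie]
  precision <- tp / cum_n[last_of_tie]
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Model configuration for an evaluation run
#'
#' @param algorithm `"LR"`, `"SVM"` or `"benchmark"` (the plain
#'   HbA1c-threshold rule; no model is fitted).
#' @param set Predictor-set name (ignored by the benchmark).
#' @param two_step Use the 2-step HbA1c-stratified strategy.
#' @param threshold Segregation / rule threshold in percent.
#' @return A `model_config` list.
#' @export
model_config <- function(algorithm = c("LR", "SVM", "benchmark"),
                         set = c("cgm", "demo", "hba1c"),
                         two_step = FALSE, threshold = 5.7) {
  algorithm <- match.arg(algorithm)
  set <- match.arg(set)
  structure(list(algorithm = algorithm, set = set,
                 two_step = isTRUE(two_step), threshold = threshold),
            class = "model_config")
}

model_label <- function(mc) {
  if (mc$algorithm == "benchmark") {
    sprintf("HbA1c >= %.1f%% rule", mc$threshold)
  } else {
    paste0(mc$set, " ", mc$algorithm, if (mc$two_step) " (2-step)")
  }
}

#' Run a repeated-subsampling evaluation experiment
#'
#' For each split: fit the configured model on the training rows (all of
#' them, regardless of HbA1c stratum), score the test rows under the
#' configured strategy, optionally restrict metric computation to the
#' HbA1c < threshold subpopulation, and compute misclassification,
#' sensitivity, specificity, ROC AUC and PRC AUC. Metrics are summarized
#' across splits as the mean with a normal-approximation 95% CI of the
#' mean. Splits where a restricted test population lacks a class are
#' excluded from the affected metric's summary, with the exclusion count
#' reported.
#'
#' The benchmark rule is scored as the binary HbA1c >= threshold
#' indicator; its ROC AUC is the two-segment trapezoid
#' (sensitivity + specificity) / 2 of its single operating point. On the
#' low-HbA1c subpopulation, where the rule makes no positive predictions,
#' its ROC and PRC AUC are reported as 0 by convention.
#'
#' @param clinical Labeled clinical tibble.
#' @param features Feature tibble (may be NULL for the demo set /
#'   benchmark).
#' @param mc A [model_config()].
#' @param n_splits,test_fraction,stratified,seed Split scheme, see
#'   [make_splits()].
#' @param population `"all"` or `"low_hba1c"` (test rows with HbA1c below
#'   the configured threshold).
#' @return An `evaluation_summary` tibble: one row per metric with
#'   `mean`, `ci_lo`, `ci_hi`, `n_splits_used`; attributes `model` and
#'   `population`.
#' @export
run_experiment <- function(clinical, features = NULL, mc = model_config(),
                           n_splits = 1000, test_fraction = 0.3,
                           stratified = TRUE, seed = 1,
                           population = c("all", "low_hba1c")) {
  population <- match.arg(population)
  benchmark <- mc$algorithm == "benchmark"
  mat <- if (benchmark) NULL else build_matrix(clinical, features, mc$set)
  truth_all <- stats::setNames(clinical$status == "prediabetes",
                               clinical$participant_id)
  hba1c_all <- stats::setNames(clinical$hba1c, clinical$participant_id)
  splits <- make_splits(clinical$participant_id, truth_all,
                        n_splits = n_splits, test_fraction = test_fraction,
                        stratified = stratified, seed = seed)
  metric_names <- c("misclassification", "sensitivity", "specificity",
                    "roc_auc", "prc_auc")
  per_split <- matrix(NA_real_, nrow = n_splits, ncol = 5,
                      dimnames = list(NULL, metric_names))
  for (i in seq_along(splits)) {
    test_ids <- splits[[i]]$test
    if (benchmark) {
      scored <- tibble::tibble(
        participant_id = test_ids,
        score = as.numeric(hba1c_all[test_ids] >= mc$threshold),
        pred = hba1c_all[test_ids] >= mc$threshold
      )
    } else {
      train_idx <- match(splits[[i]]$train, rownames(mat$x))
      test_idx <- match(test_ids, rownames(mat$x))
      model <- fit_classifier(mat$x[train_idx, , drop = FALSE],
                              mat$y[train_idx], mc$algorithm)
      scored <- if (mc$two_step) {
        score_two_step(model, mat$x[test_idx, , drop = FALSE],
                       mat$hba1c[test_idx], mc$threshold)
      } else {
        score_plain(model, mat$x[test_idx, , drop = FALSE])
      }
    }
    keep <- if (population == "low_hba1c") {
      hba1c_all[scored$participant_id] < mc$threshold
    } else rep(TRUE, nrow(scored))
    truth <- truth_all[scored$participant_id][keep]
    score <- scored$score[keep]
    pred <- scored$pred[keep]
    if (length(truth) == 0) next
    cm <- confusion_metrics(truth, pred)
    per_split[i, 1:3] <- c(cm$misclassification, cm$sensitivity,
                           cm$specificity)
    if (benchmark) {
      if (population == "low_hba1c") {
        per_split[i, 4:5] <- c(0, 0)  # reporting convention: no positives possible
      } else if (is.finite(cm$sensitivity) && is.finite(cm$specificity)) {
        per_split[i, "roc_auc"] <- (cm$sensitivity + cm$specificity) / 200
        per_split[i, "prc_auc"] <- tryCatch(prc_auc(score, truth),
                                            error = function(e) NA_real_)
      }
    } else {
      if (any(truth) && any(!truth)) {
        per_split[i, "roc_auc"] <- roc_auc(score, truth)
        per_split[i, "prc_auc"] <- prc_auc(score, truth)
      }
    }
  }
  summarize_metric <- function(v) {
    ok <- v[is.finite(v)]
    n <- length(ok)
    if (n == 0) return(c(NaN, NaN, NaN, 0))
    m <- mean(ok)
    half <- if (n > 1) 1.96 * stats::sd(ok) / sqrt(n) else 0
    c(m, m - half, m + half, n)
  }
  sm <- t(apply(per_split, 2, summarize_metric))
  out <- tibble::tibble(
    model = model_label(mc), population = population,
    metric = metric_names,
    mean = unname(sm[, 1]), ci_lo = unname(sm[, 2]), ci_hi = unname(sm[, 3]),
    n_splits_used = as.integer(sm[, 4]),
    n_excluded = as.integer(n_splits - sm[, 4])
  )
  attr(out, "model_config") <- mc
  out
}

#' Sweep the segregation threshold
#'
#' Reruns [run_experiment()] at each candidate threshold to examine how
#' the 2-step strategy's misclassification responds to where the HbA1c
#' stratification is cut.
#'
#' @inheritParams run_experiment
#' @param thresholds Numeric vector of thresholds in percent.
#' @return A tibble binding the per-threshold summaries with a
#'   `threshold` column.
#' @export
threshold_sweep <- function(clinical, features = NULL, mc = model_config(),
                            thresholds = c(5.5, 5.7, 5.9), n_splits = 200,
                            test_fraction = 0.3, seed = 1,
                            population = "all") {
  stopifnot(length(thresholds) > 0)
  dplyr::bind_rows(lapply(thresholds, function(th) {
    mci <- mc
    mci$threshold <- th
    res <- run_experiment(clinical, features, mci, n_splits = n_splits,
                          test_fraction = test_fraction, seed = seed,
                          population = population)
    res$threshold <- th
    res
  }))
}

#' Cohort summary with group comparisons
#'
#' A demographics-table style summary: median (IQR) by glycemic group for
#' continuous variables with Mann-Whitney U (Wilcoxon rank-sum) p-values,
#' n (%) with Pearson chi-square p-values for sex and ethnicity, and a
#' significance flag at the 0.05 level. When a chi-square expected cell
#' count is zero the comparison falls back to Fisher's exact test and the
#' row is flagged.
#'
#' @param clinical Labeled clinical tibble (`status` column present, two
#'   groups).
#' @param continuous_vars,categorical_vars Variables to summarize.
#' @return A tibble: `variable`, per-group summary strings, `p_value`,
#'   `test`, `significant`.
#' @export
summarize_cohort <- function(clinical,
                             continuous_vars = c("age", "bmi", "whr", "fpg",
                                                 "g2h", "hba1c"),
                             categorical_vars = c("sex", "ethnicity")) {
  groups <- c("normoglycemia", "prediabetes")
  if (!all(groups %in% clinical$status)) {
    stop("cohort summary requires both glycemic groups", call. = FALSE)
  }
  g1 <- clinical[clinical$status == groups[1], , drop = FALSE]
  g2 <- clinical[clinical$status == groups[2], , drop = FALSE]
  med_iqr <- function(x) sprintf("%.2f (%.2f-%.2f)", stats::median(x),
                                 stats::quantile(x, 0.25),
                                 stats::quantile(x, 0.75))
  rows <- lapply(continuous_vars, function(v) {
    p <- suppressWarnings(stats::wilcox.test(g1[[v]], g2[[v]])$p.value)
    tibble::tibble(variable = v, normoglycemia = med_iqr(g1[[v]]),
                   prediabetes = med_iqr(g2[[v]]), p_value = p,
                   test = "mann_whitney_u")
  })
  cat_rows <- lapply(categorical_vars, function(v) {
    tab <- table(clinical[[v]], clinical$status == "prediabetes")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher_exact_fallback"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      test <- "pearson_chi_square"
    }
    pct <- function(g) paste(sprintf("%s %d (%.1f%%)", rownames(tab),
                                     tab[, g], 100 * tab[, g] / sum(tab[, g])),
                             collapse = "; ")
    tibble::tibble(variable = v, normoglycemia = pct("FALSE"),
                   prediabetes = pct("TRUE"), p_value = p, test = test)
  })
  out <- dplyr::bind_rows(c(cat_rows, rows))
  out$significant <- out$p_value < 0.05
  out
}
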