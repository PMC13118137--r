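#' Nested predictor sets
#'
#' Three nested sets: `demo` (age, sex, BMI, waist-to-hip ratio), `cgm`
#' (demo plus the 13 CGM summary features) and `hba1c` (cgm plus the
#' numerical HbA1c value). Ethnicity is deliberately not a predictor.
#'
#' @param name `"demo"`, `"cgm"` or `"hba1c"`.
#' @return Character vector of column names in deterministic order.
#' @export
predictor_set <- function(name = c("demo", "cgm", "hba1c")) {
  name <- match.arg(name)
  demo <- c("age", "sex", "bmi", "whr")
  switch(name,
         demo = demo,
         cgm = c(demo, CGM_FEATURE_NAMES),
         hba1c = c(demo, CGM_FEATURE_NAMES, "hba1c"))
}

#' Build a model matrix and label vector from cohort tables
#'
#' Joins the clinical and feature tables on `participant_id`, encodes sex
#' as male = 0 / female = 1, orders columns per [predictor_set()] and
#' returns binary labels (prediabetes = 1). Missing values in a selected
#' column raise an error naming the participant and column.
#'
#' @param clinical Labeled clinical tibble (must carry `status`).
#' @param features Feature tibble from [extract_feature_table()] (not
#'   required for the `demo` set).
#' @param set Predictor-set name.
#' @return A list: `x` (numeric matrix), `y` (logical, TRUE =
#'   prediabetes), `hba1c` (numeric vector), `ids` (character).
#' @export
build_matrix <- function(clinical, features = NULL,
                         set = c("demo", "cgm", "hba1c")) {
  set <- match.arg(set)
  cols <- predictor_set(set)
  df <- clinical
  if (any(cols %in% CGM_FEATURE_NAMES)) {
    if (is.null(features)) stop("feature table required for set '", set, "'",
                                call. = FALSE)
    df <- dplyr::inner_join(clinical, features, by = "participant_id")
    if (nrow(df) < nrow(clinical)) {
      stop("feature table missing participants: ",
           paste(utils::head(setdiff(clinical$participant_id,
                                     features$participant_id), 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  df$sex <- ifelse(df$sex == "female", 1, 0)
  for (cl in cols) {
    if (!cl %in% names(df)) stop("missing predictor column: ", cl,
                                 call. = FALSE)
    bad <- which(!is.finite(as.numeric(df[[cl]])))
    if (length(bad) > 0) {
      stop("missing value for participant ", df$participant_id[bad[1]],
           " in column ", cl, call. = FALSE)
    }
  }
  x <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- df$participant_id
  list(x = x, y = df$status == "prediabetes",
       hba1c = df$hba1c, ids = df$participant_id)
}

#' Fit a prediabetes classifier
#'
#' Standardizes columns on the training data (zero-variance columns get
#' scale 1), then fits either an unpenalized logistic regression (`LR`)
#' or an RBF-kernel support vector machine (`SVM`, cost 1, kernel width
#' from the median pairwise-distance heuristic). LR scores are predicted
#' probabilities with decision threshold 0.5; SVM scores are signed
#' decision values, oriented so larger = more prediabetes-like, with
#' threshold 0.
#'
#' @param x Numeric training matrix.
#' @param y Logical labels (TRUE = prediabetes).
#' @param algorithm `"LR"` or `"SVM"`.
#' @return A `fitted_model` list.
#' @export
fit_classifier <- function(x, y, algorithm = c("LR", "SVM")) {
  algorithm <- match.arg(algorithm)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  if (algorithm == "LR") {
    df <- data.frame(xs, check.names = FALSE)
    df$.y <- y
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    )
    params <- list(glm = fit)
    threshold <- 0.5
  } else {
    d <- stats::dist(xs)
    sigma <- stats::median(d[d > 0])
    gamma <- 1 / (2 * sigma^2)
    yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
    fit <- e1071::svm(xs, yf, kernel = "radial", cost = 1, gamma = gamma,
                      scale = FALSE)
    params <- list(svm = fit)
    threshold <- 0
  }
  structure(list(algorithm = algorithm, columns = colnames(x),
                 center = center, scale = scale, parameters = params,
                 decision_threshold = threshold),
            class = "fitted_model")
}

model_scores <- function(model, x) {
  if (!identical(colnames(x), model$columns)) {
    stop("matrix columns do not match the fitted model's predictor set",
         call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  if (model$algorithm == "LR") {
    # rank-deficiency warnings are expected for an unpenalized fit with
    # correlated CGM features on small training sets; predictions remain
    # the standard LR output
    suppressWarnings(
      as.numeric(stats::predict(model$parameters$glm,
                                newdata = data.frame(xs, check.names = FALSE),
                                type = "response"))
    )
  } else {
    pr <- stats::predict(model$parameters$svm, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # libsvm reports the decision value for the "first/second" class pair
    # named in the column; flip so larger always means more positive
    if (grepl("^pos/", colnames(dv)[1])) as.numeric(dv[, 1]) else
      -as.numeric(dv[, 1])
  }
}

#' Score a cohort with the plain (single-step) strategy
#'
#' @param model A [fit_classifier()] model.
#' @param x Numeric matrix with the model's columns.
#' @return A `scored_cohort` tibble: `participant_id`, `score`, `pred`
#'   (logical), with attribute `strategy = "plain"`.
#' @export
score_plain <- function(model, x) {
  score <- model_scores(model, x)
  pred <- if (model$algorithm == "LR") score >= model$decision_threshold
          else score > model$decision_threshold
  out <- tibble::tibble(
    participant_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    score = score,
    pred = pred
  )
  attr(out, "strategy") <- "plain"
  out
}

#' Score a cohort with the 2-step HbA1c-stratified strategy
#'
#' Step 1 hard-classifies every row with HbA1c >= `threshold` as positive,
#' assigning it a score strictly above every model score (so the combined
#' ranking is well defined); step 2 applies the fitted model -- trained on
#' all training rows, not only the low-HbA1c stratum -- to the remaining
#' rows.
#'
#' @param model A [fit_classifier()] model.
#' @param x Numeric matrix with the model's columns.
#' @param hba1c Per-row HbA1c (percent), aligned with `x`.
#' @param threshold Segregation threshold in percent (default 5.7).
#' @return A `scored_cohort` tibble with attribute `strategy = "two_step"`.
#' @export
score_two_step <- function(model, x, hba1c, threshold = 5.7) {
  stopifnot(length(hba1c) == nrow(x))
  if (threshold < 4 || threshold > 8) {
    warning("segregation threshold ", threshold,
            "% is outside the plausible 4-8% range", call. = FALSE)
  }
  out <- score_plain(model, x)
  forced <- hba1c >= threshold
  out$score[forced] <- 1 + max(out$score)
  out$pred[forced] <- TRUE
  attr(out, "strategy") <- "two_step"
  out
}
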