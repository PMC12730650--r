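# Random-forest classification protocol: holdout split, stratified k-fold
# cross-validation on the training part, noise-robust feature input, final
# evaluation on the untouched test split (confusion, per-class metrics,
# ROC/AUC).

#' Random-forest configuration
#'
#' Hyperparameters of the classifier, in scikit-learn naming. The defaults
#' are the reference protocol's: 100 trees, Gini impurity, unbounded depth,
#' bootstrap resampling, `sqrt(p)` candidate features per split, seed 42.
#' `min_samples_split = 2` and `min_samples_leaf = 1` correspond to
#' `randomForest`'s fully grown trees (`nodesize = 1`).
#'
#' @param n_estimators Number of trees.
#' @param random_state RNG seed for training.
#' @param max_depth `NULL` for unbounded.
#' @param criterion Split criterion; `randomForest` classification trees use
#'   Gini impurity, the only supported value.
#' @param min_samples_split,min_samples_leaf Minimum node sizes.
#' @param bootstrap Sample with replacement per tree.
#' @param max_features `"sqrt"` (floor(sqrt(p)) candidate features/split) or
#'   an integer.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_estimators = 100, random_state = 42,
                      max_depth = NULL, criterion = "gini",
                      min_samples_split = 2, min_samples_leaf = 1,
                      bootstrap = TRUE, max_features = "sqrt") {
  if (criterion != "gini") {
    stop("only the Gini criterion is supported", call. = FALSE)
  }
  structure(
    list(n_estimators = as.integer(n_estimators),
         random_state = as.integer(random_state),
         max_depth = max_depth, criterion = criterion,
         min_samples_split = as.integer(min_samples_split),
         min_samples_leaf = as.integer(min_samples_leaf),
         bootstrap = isTRUE(bootstrap), max_features = max_features),
    class = "rf_config"
  )
}

class_levels <- function() c("Control", "Alzheimer")

check_feature_table <- function(features, require_two_classes = TRUE) {
  stopifnot(is.data.frame(features))
  missing <- setdiff(c(feature_columns(), "group_label"), names(features))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(features[feature_columns()])) {
    stop("feature table contains missing values", call. = FALSE)
  }
  if (require_two_classes && length(unique(features$group_label)) < 2) {
    stop("need at least two classes", call. = FALSE)
  }
  invisible(features)
}

#' Stratified holdout split
#'
#' Disjoint, exhaustive train/test partition, stratified so per-class test
#' proportions match the global `test_fraction` within one sample.
#' Deterministic given `seed`. With `group_aware = TRUE` the split is made
#' at the level of `source_id` instead of frames, so all frames of one
#' recording land on the same side (avoids frame-level pseudo-replication).
#'
#' @param features Feature tibble with a `group_label` column.
#' @param test_fraction Fraction held out, in (0, 1); default 0.20.
#' @param stratified Preserve class proportions.
#' @param seed RNG seed.
#' @param group_aware Split by `source_id` rather than by row.
#' @return List with tibbles `train` and `test`.
#' @export
holdout_split <- function(features, test_fraction = 0.20, stratified = TRUE,
                          seed = 42L, group_aware = FALSE) {
  check_feature_table(features, require_two_classes = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(features)
  test_idx <- withr::with_seed(seed, {
    if (group_aware) {
      groups <- unique(features$source_id)
      gtest <- sample(groups, max(1, round(length(groups) * test_fraction)))
      which(features$source_id %in% gtest)
    } else if (stratified) {
      unlist(lapply(split(seq_len(n), features$group_label), function(idx) {
        k <- round(length(idx) * test_fraction)
        if (length(idx) < 2) {
          stop("a class has fewer than 2 rows; cannot stratify", call. = FALSE)
        }
        sample(idx, k)
      }), use.names = FALSE)
    } else {
      sample(n, round(n * test_fraction))
    }
  })
  list(train = features[-test_idx, , drop = FALSE],
       test = features[test_idx, , drop = FALSE])
}

fit_rf <- function(x, y, config) {
  mtry <- if (identical(config$max_features, "sqrt")) {
    max(1, floor(sqrt(ncol(x))))
  } else as.integer(config$max_features)
  maxnodes <- if (is.null(config$max_depth)) NULL else 2^config$max_depth
  randomForest::randomForest(
    x = x, y = y, ntree = config$n_estimators, mtry = mtry,
    replace = config$bootstrap, nodesize = config$min_samples_leaf,
    maxnodes = maxnodes
  )
}

#' Train the random forest
#'
#' Fits the ensemble on the feature columns of `train` with the exact
#' hyperparameters of `config`; refitting with the same data and config
#' reproduces identical predictions (training is wrapped in the config's
#' `random_state`).
#'
#' @param train Training feature tibble.
#' @param config An [rf_config()].
#' @return An object of class `vib_rf` wrapping the fitted ensemble.
#' @export
train_rf <- function(train, config = rf_config()) {
  check_feature_table(train)
  x <- as.data.frame(train[feature_columns()])
  y <- factor(train$group_label, levels = class_levels())
  if (any(is.na(y))) {
    stop("group labels must be in {", paste(class_levels(), collapse = ", "),
         "}", call. = FALSE)
  }
  fit <- withr::with_seed(config$random_state, fit_rf(x, y, config))
  structure(list(fit = fit, config = config, features = feature_columns(),
                 n_train = nrow(train)),
            class = "vib_rf")
}

#' @export
print.vib_rf <- function(x, ...) {
  cat(sprintf("<vib_rf> %d trees on %d rows x %d features\n",
              x$config$n_estimators, x$n_train, length(x$features)))
  invisible(x)
}

#' Ensemble vote scores
#'
#' Fraction of trees voting for the positive class (`"Alzheimer"`); the
#' score swept to build the ROC curve.
#'
#' @param model A [train_rf()] fit.
#' @param newdata Feature tibble.
#' @return Numeric scores in [0, 1].
#' @export
rf_scores <- function(model, newdata) {
  stopifnot(inherits(model, "vib_rf"))
  p <- stats::predict(model$fit,
                      newdata = as.data.frame(newdata[model$features]),
                      type = "prob")
  as.numeric(p[, "Alzheimer"])
}

#' Stratified k-fold cross-validation
#'
#' Partitions the training rows into `k` stratified folds (class proportions
#' preserved within one sample per fold), trains on k-1 folds, scores
#' accuracy on the held-out fold, and summarises mean, standard deviation
#' and two 95% interval forms: `ci95_normal` (`mean +/- 1.96 sd / sqrt(k)`)
#' and `ci95_sd` (`mean +/- sd`).
#'
#' @param train Feature tibble.
#' @param k Number of folds (>= 2); default 5.
#' @param config An [rf_config()].
#' @param seed RNG seed for the fold assignment.
#' @return An object of class `vib_cv`: list with `fold_accuracy`, `mean`,
#'   `sd`, `ci95_normal`, `ci95_sd`, `k`.
#' @export
crossval <- function(train, k = 5, config = rf_config(), seed = 42L) {
  check_feature_table(train)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  counts <- table(train$group_label)
  if (any(counts < k)) {
    stop("every class needs at least k rows for k-fold CV", call. = FALSE)
  }
  fold <- integer(nrow(train))
  fold[] <- withr::with_seed(seed, {
    f <- integer(nrow(train))
    for (idx in split(seq_len(nrow(train)), train$group_label)) {
      f[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  acc <- vapply(seq_len(k), function(i) {
    fit <- train_rf(train[fold != i, , drop = FALSE], config)
    scores <- rf_scores(fit, train[fold == i, , drop = FALSE])
    pred <- hard_labels(scores)
    mean(pred == train$group_label[fold == i])
  }, numeric(1))
  m <- mean(acc); s <- stats::sd(acc)
  structure(
    list(fold_accuracy = acc, mean = m, sd = s,
         ci95_normal = c(m - 1.96 * s / sqrt(k), m + 1.96 * s / sqrt(k)),
         ci95_sd = c(m - s, m + s), k = k),
    class = "vib_cv"
  )
}

#' @export
print.vib_cv <- function(x, ...) {
  cat(sprintf("<vib_cv> %d-fold accuracy %.4f +/- %.4f (mean +/- sd: %.4f-%.4f)\n",
              x$k, x$mean, x$sd, x$ci95_sd[1], x$ci95_sd[2]))
  invisible(x)
}

# vote fraction > 0.5 -> Alzheimer; exact ties go to Control (deterministic)
hard_labels <- function(scores) {
  ifelse(scores > 0.5, "Alzheimer", "Control")
}

#' Classification metrics from a confusion matrix
#'
#' Standard binary metrics recomputed from raw counts: per-class precision
#' (also reported as `class_accuracy`, the name some reports use for this
#' column), recall, F1 and specificity, plus overall accuracy. Rows of
#' `confusion` are true classes, columns predicted, order
#' (Control, Alzheimer).
#'
#' @param confusion 2x2 numeric matrix of counts.
#' @return List with `per_class` (tibble) and `overall_accuracy`.
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == c(2, 2)), all(confusion >= 0))
  lv <- class_levels()
  rows <- lapply(seq_len(2), function(c) {
    tp <- confusion[c, c]
    fn <- sum(confusion[c, ]) - tp
    fp <- sum(confusion[, c]) - tp
    tn <- sum(confusion) - tp - fn - fp
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(precision + recall > 0)) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    tibble::tibble(class = lv[c], precision = precision,
                   class_accuracy = precision, recall = recall, f1 = f1,
                   specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                   support = sum(confusion[c, ]))
  })
  list(per_class = dplyr::bind_rows(rows),
       overall_accuracy = sum(diag(confusion)) / sum(confusion))
}

#' ROC curve and AUC from scores
#'
#' Sweeps all score thresholds, taking `"Alzheimer"` as the positive class;
#' AUC by the trapezoidal rule. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric scores (higher = more Alzheimer-like).
#' @param labels True class labels.
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- labels == "Alzheimer"
  if (!any(pos) || all(pos)) {
    stop("ROC undefined: test set contains a single class", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a fitted model on a test set
#'
#' @param model A [train_rf()] fit.
#' @param test Test feature tibble (both classes present for the ROC).
#' @param cv Optional [crossval()] summary to attach.
#' @return An object of class `vib_report`: confusion matrix, per-class
#'   metrics tibble, overall accuracy, ROC tibble, AUC, optional CV summary
#'   and the `|cv_mean - test_accuracy|` overfitting gap.
#' @export
evaluate_rf <- function(model, test, cv = NULL) {
  stopifnot(inherits(model, "vib_rf"))
  check_feature_table(test, require_two_classes = FALSE)
  scores <- rf_scores(model, test)
  pred <- factor(hard_labels(scores), levels = class_levels())
  truth <- factor(test$group_label, levels = class_levels())
  confusion <- table(truth = truth, predicted = pred)
  confusion <- matrix(as.numeric(confusion), 2, 2,
                      dimnames = list(true = class_levels(),
                                      predicted = class_levels()))
  metrics <- confusion_metrics(confusion)
  roc <- if (length(unique(test$group_label)) == 2) {
    roc_curve(scores, test$group_label)
  } else list(roc = NULL, auc = NA_real_)
  structure(
    list(confusion = confusion,
         per_class = metrics$per_class,
         overall_accuracy = metrics$overall_accuracy,
         roc = roc$roc, auc = roc$auc,
         cv = cv,
         overfitting_gap = if (!is.null(cv)) {
           abs(cv$mean - metrics$overall_accuracy)
         } else NA_real_,
         n_test = nrow(test), scores = scores),
    class = "vib_report"
  )
}

#' @export
print.vib_report <- function(x, ...) {
  cat("<vib_report>\n")
  cat(sprintf("  test accuracy %.4f, AUC %.4f (n = %d)\n",
              x$overall_accuracy, x$auc, x$n_test))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV accuracy %.4f +/- %.4f; overfitting gap %.4f\n",
                x$cv$mean, x$cv$sd, x$overfitting_gap))
  }
  print(x$confusion)
  invisible(x)
}

#' Run the full classification protocol on a feature table
#'
#' Holdout split (default 80/20), stratified k-fold cross-validation on the
#' training part, final fit on all training rows, and evaluation on the
#' untouched test split. `mode = "frame"` splits at the frame level, which
#' replicates the reference protocol but treats correlated frames of one
#' recording as independent (pseudo-replication; a leakage note is emitted);
#' `mode = "grouped"` splits by `source_id`.
#'
#' @param features Labeled feature tibble ([features_from_frames()] rows for
#'   both groups).
#' @param config An [rf_config()].
#' @param test_fraction Holdout fraction.
#' @param k CV folds.
#' @param seed Seed for the split and fold assignment.
#' @param mode `"frame"` (frame-level split) or `"grouped"`.
#' @param quiet Suppress the leakage message.
#' @return A `vib_report` (see [evaluate_rf()]), with the split sizes in
#'   `$n_train` / `$n_test`.
#' @export
run_protocol <- function(features, config = rf_config(), test_fraction = 0.20,
                         k = 5, seed = 42L, mode = c("frame", "grouped"),
                         quiet = FALSE) {
  mode <- match.arg(mode)
  check_feature_table(features)
  if (mode == "frame" && !quiet) {
    message("frame-level split: frames of one recording fall on both sides ",
            "of the split (pseudo-replication); use mode = \"grouped\" for ",
            "leakage-free estimates")
  }
  split <- holdout_split(features, test_fraction = test_fraction,
                         stratified = mode == "frame", seed = seed,
                         group_aware = mode == "grouped")
  cv <- crossval(split$train, k = k, config = config, seed = seed)
  model <- train_rf(split$train, config)
  report <- evaluate_rf(model, split$test, cv = cv)
  report$n_train <- nrow(split$train)
  report$mode <- mode
  report$model <- model
  report
}
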