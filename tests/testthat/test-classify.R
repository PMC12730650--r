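# Random-forest protocol: splits, cross-validation, metrics, ROC/AUC.

# well-separated two-cluster toy features
make_clusters <- function(n_per_class, sep = 8, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(label, centre) {
      tibble::tibble(
        frame_index = seq_len(n_per_class), time_s = seq_len(n_per_class) / 10,
        group_label = label, source_id = paste0(label, "-src"),
        active_area = rnorm(n_per_class, centre, 1),
        entropy = rnorm(n_per_class, centre / 10, 0.05),
        fractal_dim = runif(n_per_class, 1, 2),
        centroid_x = rnorm(n_per_class, 50, 5),
        centroid_y = rnorm(n_per_class, 40, 5),
        step_disp = abs(rnorm(n_per_class, 3, 1)),
        valid = TRUE
      )
    }
    dplyr::bind_rows(mk("Control", 20), mk("Alzheimer", 20 + sep))
  })
}

test_that("metrics recomputed from the reference confusion matrix", {
  confusion <- matrix(c(645, 122, 108, 637), nrow = 2,
                      dimnames = list(true = c("Control", "Alzheimer"),
                                      predicted = c("Control", "Alzheimer")))
  m <- confusion_metrics(confusion)
  expect_equal(round(m$overall_accuracy, 2), 0.85)
  pc <- m$per_class
  expect_equal(round(pc$recall[pc$class == "Control"], 2), 0.86)
  expect_equal(round(pc$recall[pc$class == "Alzheimer"], 2), 0.84)
  expect_equal(round(pc$f1, 2), c(0.85, 0.85))
  expect_equal(round(pc$precision, 2), c(0.84, 0.86))
  expect_equal(round(pc$specificity, 2), c(0.84, 0.86))
  expect_equal(pc$support, c(753, 759))
})

test_that("every metric is consistent with its confusion matrix", {
  set.seed(77)
  for (i in 1:10) {
    cm <- matrix(sample(0:200, 4, replace = TRUE), 2, 2)
    if (any(rowSums(cm) == 0) || any(colSums(cm) == 0)) next
    m <- confusion_metrics(cm)
    pc <- m$per_class
    for (c in 1:2) {
      tp <- cm[c, c]
      expect_equal(pc$recall[c], tp / sum(cm[c, ]))
      expect_equal(pc$precision[c], tp / sum(cm[, c]))
      expect_equal(pc$specificity[c],
                   (sum(cm) - sum(cm[c, ]) - sum(cm[, c]) + tp) /
                     (sum(cm) - sum(cm[c, ])))
    }
    expect_equal(m$overall_accuracy, sum(diag(cm)) / sum(cm))
  }
})

test_that("stratified holdout splits are exact partitions with preserved ratios", {
  f <- make_clusters(50)
  sp <- holdout_split(f, test_fraction = 0.2, seed = 3)
  expect_equal(nrow(sp$test), 20)
  expect_equal(as.numeric(table(sp$test$group_label)), c(10, 10))
  expect_equal(nrow(sp$train) + nrow(sp$test), 100)

  key <- function(d) paste(d$group_label, d$frame_index)
  expect_setequal(c(key(sp$train), key(sp$test)), key(f))
  expect_length(intersect(key(sp$train), key(sp$test)), 0)

  sp2 <- holdout_split(f, test_fraction = 0.2, seed = 3)
  expect_identical(sp$test, sp2$test)
  expect_error(holdout_split(f, test_fraction = 1.2), "0, 1")
})

test_that("group-aware splitting keeps every source on one side", {
  f <- make_clusters(30)
  f$source_id <- rep(paste0("src", 1:6), length.out = nrow(f))
  sp <- holdout_split(f, test_fraction = 0.3, seed = 5, group_aware = TRUE)
  expect_length(intersect(unique(sp$train$source_id),
                          unique(sp$test$source_id)), 0)
  expect_setequal(c(unique(sp$train$source_id), unique(sp$test$source_id)),
                  paste0("src", 1:6))
})

test_that("cross-validation is perfect on separable clusters", {
  f <- make_clusters(30)
  cv <- crossval(f, k = 5, config = rf_config(n_estimators = 50), seed = 2)
  expect_equal(cv$mean, 1)
  expect_equal(cv$sd, 0)
  expect_length(cv$fold_accuracy, 5)
  expect_equal(cv$ci95_sd, c(1, 1))
})

test_that("stratified folds preserve class ratios within one sample", {
  f <- make_clusters(33)
  fold <- withr::with_seed(11, {
    ff <- integer(nrow(f))
    for (idx in split(seq_len(nrow(f)), f$group_label)) {
      ff[sample(idx)] <- rep_len(1:5, length(idx))
    }
    ff
  })
  for (k in 1:5) {
    tab <- table(f$group_label[fold == k])
    expect_lte(abs(tab[1] - tab[2]), 1)
  }
  expect_error(crossval(make_clusters(3), k = 5), "at least k")
})

test_that("label-permuted features classify at chance", {
  f <- make_clusters(400)
  f$group_label <- withr::with_seed(9, sample(f$group_label))
  cv <- crossval(f, k = 5, config = rf_config(n_estimators = 50), seed = 4)
  expect_gt(cv$mean, 0.42)
  expect_lt(cv$mean, 0.58)
})

hard_labels_pkg <- function(model, data) {
  ifelse(rf_scores(model, data) > 0.5, "Alzheimer", "Control")
}
class_levels_pkg <- function() c("Control", "Alzheimer")

test_that("training is deterministic and rejects degenerate input", {
  f <- make_clusters(25)
  m1 <- train_rf(f)
  m2 <- train_rf(f)
  expect_identical(rf_scores(m1, f), rf_scores(m2, f))
  expect_equal(mean(hard_labels_pkg(m1, f) == f$group_label), 1)
  one <- dplyr::filter(f, .data$group_label == "Control")
  expect_error(train_rf(one), "two classes")
})

test_that("evaluation reproduces perfect and chance endpoints", {
  f <- make_clusters(40)
  sp <- holdout_split(f, 0.25, seed = 6)
  model <- train_rf(sp$train)
  rep <- evaluate_rf(model, sp$test)
  expect_equal(rep$overall_accuracy, 1)
  expect_equal(rep$auc, 1)
  expect_equal(unname(diag(rep$confusion)),
               as.numeric(table(sp$test$group_label)[class_levels_pkg()]))

  # uninformative constant scores give AUC 1/2
  rc <- roc_curve(rep(0.5, 40), rep(c("Control", "Alzheimer"), 20))
  expect_equal(rc$auc, 0.5)
})

test_that("AUC matches pROC and is invariant to monotone transforms", {
  set.seed(13)
  labels <- rep(c("Control", "Alzheimer"), each = 60)
  scores <- c(rnorm(60, 0.4, 0.15), rnorm(60, 0.6, 0.15))
  scores <- pmin(pmax(scores, 0), 1)
  rc <- roc_curve(scores, labels)
  ref <- pROC::auc(pROC::roc(response = labels, predictor = scores,
                             levels = c("Control", "Alzheimer"),
                             direction = "<", quiet = TRUE))
  expect_equal(rc$auc, as.numeric(ref), tolerance = 1e-12)
  rc2 <- roc_curve(scores^3, labels)
  expect_equal(rc2$auc, rc$auc, tolerance = 1e-12)
  expect_error(roc_curve(scores, rep("Control", 120)), "single class")
})

test_that("the full protocol report is complete and self-consistent", {
  f <- make_clusters(60, sep = 3, seed = 21)
  rep <- run_protocol(f, config = rf_config(n_estimators = 50),
                      seed = 5, quiet = TRUE)
  expect_s3_class(rep, "vib_report")
  g <- glance(rep)
  expect_true(all(c("accuracy", "auc", "cv_mean", "cv_sd",
                    "overfitting_gap", "n_train", "n_test") %in% names(g)))
  expect_equal(g$n_train + g$n_test, 120)
  expect_equal(rep$overall_accuracy,
               sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_equal(rep$overfitting_gap, abs(rep$cv$mean - rep$overall_accuracy))
  td <- tidy(rep)
  expect_equal(td$class, c("Control", "Alzheimer"))
  expect_message(run_protocol(f, config = rf_config(n_estimators = 20),
                              seed = 5), "pseudo-replication")
})
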