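#' Leave-2-Opposite-Groups-Out cross-validation splits
#'
#' Builds one fold per pair of opposite-class images: the test set holds all
#' nuclei of one image from each class, the training set all remaining
#' images. All masks derived from one image fall on one side of the split,
#' which guards against image-level batch effects.
#'
#' @param features feature table with `image_id` and `condition` columns
#'   (binary condition).
#' @return List of folds, each a list with `test_pair` (named character
#'   vector of the two test image ids) and `train_image_ids`.
#' @export
l2ogo_splits <- function(features) {
  cls <- sort(unique(features$condition))
  if (length(cls) != 2)
    stop("L2OGO requires exactly 2 classes, found ", length(cls))
  imgs_by_class <- lapply(cls, function(cc)
    unique(features$image_id[features$condition == cc]))
  if (any(lengths(imgs_by_class) == 0)) stop("a class has zero images")
  all_imgs <- unique(features$image_id)
  if (length(all_imgs) < 3)
    stop("degenerate L2OGO: need at least 3 images so training is non-empty")
  folds <- list()
  for (a in imgs_by_class[[1]])
    for (b in imgs_by_class[[2]]) {
      folds[[length(folds) + 1]] <- list(
        test_pair = stats::setNames(c(a, b), cls),
        train_image_ids = setdiff(all_imgs, c(a, b)))
    }
  folds
}

#' Balance classes by random uniform sub-sampling
#'
#' Downsamples the majority class to the minority count, uniformly without
#' replacement; deterministic given the seed.
#'
#' @param rows training rows (feature table subset) with a `condition`
#'   column.
#' @param seed integer seed.
#' @return The balanced subset of `rows`.
#' @export
balance_classes <- function(rows, seed = 1) {
  cls <- unique(rows$condition)
  n_min <- min(table(rows$condition))
  with_seed(seed, {
    keep <- unlist(lapply(cls, function(cc) {
      idx <- which(rows$condition == cc)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }))
  })
  rows[sort(keep), , drop = FALSE]
}

#' Classifier presets
#'
#' `"fibroblast-gb"`: stochastic gradient boosting with 1,500 base
#' learners, maximum tree depth 8, subsampling rate 0.5 (the configuration
#' that separates serum-starved from proliferating fibroblasts best).
#' `"pc3-rf"`: random forest with 1,000 trees, maximum depth 12, and 40% of
#' the features considered per split (the PC3 epithelial/mesenchymal
#' preset). `"fast-rf"`: a light 200-tree forest for pipeline tests and
#' small synthetic populations.
#'
#' @param preset preset name, or `"custom"` combined with `...` overrides.
#' @param ... fields overriding the preset (e.g. `num_trees`).
#' @return A `model_config` list with an `engine` field (`"xgboost"` or
#'   `"ranger"`).
#' @export
model_config <- function(preset = c("fast-rf", "fibroblast-gb", "pc3-rf",
                                    "custom"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    "fibroblast-gb" = list(engine = "xgboost", n_rounds = 1500,
                           max_depth = 8, subsample = 0.5, eta = 0.1),
    "pc3-rf" = list(engine = "ranger", num_trees = 1000, max_depth = 12,
                    mtry_fraction = 0.4),
    "fast-rf" = list(engine = "ranger", num_trees = 200, max_depth = 0,
                     mtry_fraction = 0.4),
    "custom" = list(engine = "ranger", num_trees = 500, max_depth = 0,
                    mtry_fraction = 0.4))
  over <- list(...)
  cfg[names(over)] <- over
  cfg$preset <- preset
  structure(cfg, class = "model_config")
}

#' Fit a classifier on training cells and score test cells
#'
#' Trains the configured model on the (image-disjoint) training rows and
#' returns the predicted probability of the positive class (the
#' alphabetically larger condition label) for every test cell.
#'
#' @param train,test feature-table subsets; train must contain both classes.
#' @param config a [model_config()].
#' @param seed integer seed controlling the fit.
#' @return List with `prob` (per-test-cell positive-class probability),
#'   `positive_class`, `importance` (named impurity/gain importances), and
#'   `truth` (test labels).
#' @export
fit_and_score_cells <- function(train, test, config = model_config(),
                                seed = 1) {
  cls <- sort(unique(train$condition))
  if (length(cls) < 2) stop("training set contains a single class")
  pos <- cls[2]
  feats <- feature_names()
  xtr <- as.matrix(train[, feats])
  xte <- as.matrix(test[, feats, drop = FALSE])
  ytr <- as.integer(train$condition == pos)
  if (config$engine == "xgboost") {
    dtr <- xgboost::xgb.DMatrix(xtr, label = ytr)
    with_seed(seed, {
      booster <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = config$max_depth,
                      subsample = config$subsample, eta = config$eta,
                      nthread = 1),
        data = dtr, nrounds = config$n_rounds, verbose = 0)
    })
    prob <- stats::predict(booster, xgboost::xgb.DMatrix(xte))
    imp <- xgboost::xgb.importance(model = booster)
    importance <- stats::setNames(rep(0, length(feats)), feats)
    importance[imp$Feature] <- imp$Gain
  } else {
    mtry <- max(1L, floor(config$mtry_fraction * length(feats)))
    fit <- ranger::ranger(
      x = xtr, y = factor(train$condition, levels = cls),
      probability = TRUE, num.trees = config$num_trees,
      max.depth = config$max_depth, mtry = mtry,
      importance = "impurity", seed = seed, num.threads = 1)
    prob <- stats::predict(fit, data = xte,
                           num.threads = 1)$predictions[, pos]
    importance <- fit$variable.importance
    importance <- importance / max(sum(importance), .Machine$double.eps)
  }
  list(prob = as.numeric(prob), positive_class = pos,
       importance = importance, truth = test$condition)
}

#' Binary classification metrics
#'
#' Accuracy, precision, sensitivity, and AUC (by the rank statistic, so tied
#' scores contribute 1/2). The positive class drives precision/sensitivity;
#' hard labels use the 0.5 probability threshold.
#'
#' @param prob positive-class probabilities.
#' @param truth true labels.
#' @param positive_class label treated as positive.
#' @return Named numeric vector `accuracy`, `precision`, `sensitivity`,
#'   `auc`. Precision is `NA` when nothing is predicted positive.
#' @export
evaluate_metrics <- function(prob, truth, positive_class) {
  y <- truth == positive_class
  pred <- prob >= 0.5
  acc <- mean(pred == y)
  prec <- if (sum(pred) > 0) sum(pred & y) / sum(pred) else NA_real_
  sens <- if (sum(y) > 0) sum(pred & y) / sum(y) else NA_real_
  auc <- if (length(unique(y)) == 2) {
    r <- rank(prob)
    n1 <- sum(y)
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * (length(y) - n1))
  } else NA_real_
  c(accuracy = acc, precision = prec, sensitivity = sens, auc = auc)
}

#' Cell-set classification by majority vote
#'
#' Bootstraps small sets of cells from each test image (each set therefore
#' has a single true label), labels a set by the majority of its members'
#' hard labels (ties broken by the mean probability), and scores a set by
#' the mean member probability. Metrics are computed per bootstrap
#' repetition over all sets of that repetition, then averaged: even when a
#' minority of cells is misclassified, the set label remains correct.
#'
#' @param prob per-cell positive-class probabilities of one fold's test
#'   cells.
#' @param truth per-cell true labels.
#' @param image_id per-cell source image (sets never mix images).
#' @param positive_class label treated as positive.
#' @param set_size cells per set; odd sizes avoid voting ties.
#' @param n_bootstrap bootstrap repetitions (default 1000).
#' @param seed integer seed.
#' @return Named numeric vector with mean `accuracy`, `precision`,
#'   `sensitivity`, `auc` across repetitions.
#' @export
classify_sets <- function(prob, truth, image_id, positive_class,
                          set_size = 9, n_bootstrap = 1000, seed = 1) {
  if (set_size < 1) stop("set_size must be >= 1")
  if (set_size %% 2 == 0)
    warning("even set_size is tie-prone; ties are broken by mean probability")
  imgs <- unique(image_id)
  hard <- prob >= 0.5
  with_seed(seed, {
    # per repetition and image: one drawn set
    set_prob <- matrix(0, n_bootstrap, length(imgs))
    set_vote <- matrix(0, n_bootstrap, length(imgs))
    set_truth <- character(length(imgs))
    for (g in seq_along(imgs)) {
      idx <- which(image_id == imgs[g])
      set_truth[g] <- truth[idx[1]]
      draw <- matrix(sample(idx, n_bootstrap * set_size, replace = TRUE),
                     n_bootstrap, set_size)
      set_prob[, g] <- rowMeans(matrix(prob[draw], n_bootstrap))
      set_vote[, g] <- rowMeans(matrix(hard[draw], n_bootstrap))
    }
  })
  y <- set_truth == positive_class
  # majority vote with mean-probability tie-break
  pred <- set_vote > 0.5 | (set_vote == 0.5 & set_prob >= 0.5)
  acc <- rowMeans(pred == matrix(y, n_bootstrap, length(imgs), byrow = TRUE))
  npos_pred <- rowSums(pred)
  tp <- rowSums(pred[, y, drop = FALSE])
  prec <- ifelse(npos_pred > 0, tp / npos_pred, NA_real_)
  sens <- tp / max(sum(y), 1)
  auc <- rep(NA_real_, n_bootstrap)
  if (length(unique(y)) == 2) {
    auc <- apply(set_prob, 1, function(s) {
      r <- rank(s)
      n1 <- sum(y)
      (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * (length(y) - n1))
    })
  }
  c(accuracy = mean(acc), precision = mean(prec, na.rm = TRUE),
    sensitivity = mean(sens), auc = mean(auc))
}

#' Evaluate condition discrimination under L2OGO cross-validation
#'
#' Runs the full loop: per fold, balance the training classes, fit the
#' model, score single cells, and bootstrap cell-set metrics for each
#' requested set size. Set size 1 rows report single-cell performance.
#'
#' @param features feature table from [build_feature_table()].
#' @param config a [model_config()].
#' @param set_sizes integer vector of set sizes (default odd 3 to 31, the
#'   range over which set classification is usually swept).
#' @param n_bootstrap bootstrap repetitions per fold and set size.
#' @param seed integer seed; fold seeds are derived from it.
#' @return List with `metrics` (data.frame: fold x set_size rows),
#'   `summary` (mean and SD across folds per set size), `importance`
#'   (mean normalized importances, sorted), and `positive_class`.
#' @export
evaluate_l2ogo <- function(features, config = model_config(),
                           set_sizes = seq(3, 31, by = 2),
                           n_bootstrap = 1000, seed = 1) {
  folds <- l2ogo_splits(features)
  rows <- list()
  imp_acc <- NULL
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    train <- features[features$image_id %in% fold$train_image_ids, ]
    test <- features[features$image_id %in% fold$test_pair, ]
    train <- balance_classes(train, seed = seed + 7 * fi)
    fit <- fit_and_score_cells(train, test, config, seed = seed + 13 * fi)
    imp_acc <- if (is.null(imp_acc)) fit$importance else imp_acc + fit$importance
    single <- evaluate_metrics(fit$prob, fit$truth, fit$positive_class)
    rows[[length(rows) + 1]] <- data.frame(
      fold = fi, set_size = 1, t(single))
    for (s in set_sizes) {
      m <- classify_sets(fit$prob, fit$truth, test$image_id,
                         fit$positive_class, set_size = s,
                         n_bootstrap = n_bootstrap, seed = seed + 97 * fi + s)
      rows[[length(rows) + 1]] <- data.frame(fold = fi, set_size = s, t(m))
    }
  }
  metrics <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(metrics, metrics$set_size), function(d) {
    data.frame(set_size = d$set_size[1],
               accuracy = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
               precision = mean(d$precision, na.rm = TRUE),
               sensitivity = mean(d$sensitivity, na.rm = TRUE),
               auc = mean(d$auc, na.rm = TRUE), auc_sd = stats::sd(d$auc))
  }))
  summ <- summ[order(summ$set_size), ]
  rownames(summ) <- NULL
  importance <- imp_acc / sum(imp_acc)
  list(metrics = metrics, summary = summ,
       importance = sort(importance, decreasing = TRUE),
       positive_class = sort(unique(features$condition))[2],
       n_folds = length(folds))
}

#' Mean cross-validated feature importance
#'
#' @param l2ogo_result result of [evaluate_l2ogo()].
#' @param top number of features to return.
#' @return Data.frame of feature names and mean normalized importance
#'   (summing to 1 over all features), in decreasing order.
#' @export
feature_importance <- function(l2ogo_result, top = length(l2ogo_result$importance)) {
  imp <- l2ogo_result$importance
  data.frame(feature = names(imp), importance = as.numeric(imp),
             row.names = NULL)[seq_len(min(top, length(imp))), ]
}
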