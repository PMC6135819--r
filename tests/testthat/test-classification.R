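test_that("L2OGO builds one fold per opposite-class image pair", {
  tab <- fake_feature_table(n_per_image = 4, images_a = 2, images_b = 3)
  folds <- l2ogo_splits(tab)
  expect_length(folds, 6)
  all_imgs <- unique(tab$image_id)
  for (f in folds) {
    pair_cls <- tab$condition[match(f$test_pair, tab$image_id)]
    expect_setequal(pair_cls, c("A", "B"))
    expect_length(intersect(f$test_pair, f$train_image_ids), 0)
    expect_setequal(c(f$test_pair, f$train_image_ids), all_imgs)
  }
})

test_that("L2OGO matches exhaustive pair enumeration on random layouts", {
  set.seed(13)
  for (rep in 1:5) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    if (na + nb < 3) next
    tab <- fake_feature_table(n_per_image = 2, images_a = na, images_b = nb)
    folds <- l2ogo_splits(tab)
    expect_length(folds, na * nb)
    pairs <- vapply(folds, function(f) paste(sort(f$test_pair), collapse = "|"), "")
    want <- as.vector(outer(paste0("A", seq_len(na)), paste0("B", seq_len(nb)),
                            function(a, b) paste(a, b, sep = "|")))
    expect_setequal(pairs, want)
  }
})

test_that("degenerate L2OGO layouts are rejected", {
  tab <- fake_feature_table(n_per_image = 3, images_a = 1, images_b = 1)
  expect_error(l2ogo_splits(tab), "at least 3 images")
  one <- fake_feature_table(n_per_image = 3, images_a = 2, images_b = 2)
  one$condition <- "A"
  expect_error(l2ogo_splits(one), "2 classes")
})

test_that("class balancing downsamples to the minority count", {
  tab <- fake_feature_table(n_per_image = 1, images_a = 1, images_b = 1)
  rows <- rbind(tab[rep(1, 310), ], tab[rep(2, 148), ])
  rows$object_id <- seq_len(nrow(rows))
  bal <- balance_classes(rows, seed = 4)
  expect_equal(unname(table(bal$condition)["A"]), 148)
  expect_equal(unname(table(bal$condition)["B"]), 148)
  expect_identical(balance_classes(rows, seed = 4), bal)
  even <- rbind(tab[rep(1, 20), ], tab[rep(2, 20), ])
  even$object_id <- seq_len(nrow(even))
  expect_equal(nrow(balance_classes(even, seed = 1)), 40)
})

test_that("binary metrics match a hand-worked confusion case", {
  # TP = 2, FP = 1, FN = 1, TN = 2
  truth <- c("B", "B", "B", "A", "A", "A")
  prob <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1)
  m <- evaluate_metrics(prob, truth, positive_class = "B")
  expect_equal(unname(m["accuracy"]), 4 / 6)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["sensitivity"]), 2 / 3)
  perfect <- evaluate_metrics(c(1, 1, 0, 0), c("B", "B", "A", "A"), "B")
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  const <- evaluate_metrics(rep(0.5, 6), truth, "B")
  expect_equal(unname(const["auc"]), 0.5)
})

test_that("classifiers separate separable features and not permuted ones", {
  tab <- fake_feature_table(n_per_image = 15, delta = 6, sd = 0.5, seed = 2)
  folds <- l2ogo_splits(tab)
  f <- folds[[1]]
  train <- tab[tab$image_id %in% f$train_image_ids, ]
  test <- tab[tab$image_id %in% f$test_pair, ]
  fit <- fit_and_score_cells(train, test, model_config("fast-rf"), seed = 1)
  m <- evaluate_metrics(fit$prob, fit$truth, fit$positive_class)
  expect_gt(unname(m["auc"]), 0.99)
  # permuted labels: chance-level discrimination
  set.seed(5)
  trainp <- train
  trainp$condition <- sample(trainp$condition)
  fitp <- fit_and_score_cells(trainp, test, model_config("fast-rf"), seed = 1)
  mp <- evaluate_metrics(fitp$prob, fitp$truth, fitp$positive_class)
  expect_lt(abs(unname(mp["auc"]) - 0.5), 0.3)
  # determinism
  fit2 <- fit_and_score_cells(train, test, model_config("fast-rf"), seed = 1)
  expect_identical(fit$prob, fit2$prob)
  single <- train[train$condition == "A", ]
  expect_error(fit_and_score_cells(single, test, model_config("fast-rf")),
               "single class")
})

test_that("model presets expose the published hyperparameters", {
  gb <- model_config("fibroblast-gb")
  expect_equal(gb$engine, "xgboost")
  expect_equal(gb$n_rounds, 1500)
  expect_equal(gb$max_depth, 8)
  expect_equal(gb$subsample, 0.5)
  rf <- model_config("pc3-rf")
  expect_equal(rf$engine, "ranger")
  expect_equal(rf$num_trees, 1000)
  expect_equal(rf$max_depth, 12)
  expect_equal(rf$mtry_fraction, 0.4)
  custom <- model_config("fast-rf", num_trees = 50)
  expect_equal(custom$num_trees, 50)
})

test_that("the gradient-boosting preset engine trains and scores", {
  tab <- fake_feature_table(n_per_image = 10, delta = 6, sd = 0.5, seed = 3)
  folds <- l2ogo_splits(tab)
  f <- folds[[1]]
  cfg <- model_config("fibroblast-gb", n_rounds = 40)  # truncated for speed
  fit <- fit_and_score_cells(tab[tab$image_id %in% f$train_image_ids, ],
                             tab[tab$image_id %in% f$test_pair, ], cfg,
                             seed = 2)
  expect_true(all(fit$prob >= 0 & fit$prob <= 1))
  m <- evaluate_metrics(fit$prob, fit$truth, fit$positive_class)
  expect_gt(unname(m["auc"]), 0.95)
})

test_that("a perfect per-cell classifier yields perfect sets at any size", {
  truth <- rep(c("A", "B"), each = 40)
  imgs <- rep(c("iA", "iB"), each = 40)
  prob <- ifelse(truth == "B", 0.95, 0.05)
  for (s in c(3, 9, 31)) {
    r <- classify_sets(prob, truth, imgs, "B", set_size = s,
                       n_bootstrap = 50, seed = 1)
    expect_equal(unname(r["accuracy"]), 1)
    expect_equal(unname(r["auc"]), 1)
  }
  expect_warning(classify_sets(prob, truth, imgs, "B", set_size = 4,
                               n_bootstrap = 10, seed = 1), "tie")
})

test_that("majority voting tracks the exact binomial tail", {
  # i.i.d. per-cell accuracy 0.7, sets of 19, majority >= 10 correct
  set.seed(17)
  n_cells <- 400
  truth <- rep(c("A", "B"), each = n_cells)
  imgs <- rep(c("iA1", "iB1"), each = n_cells)
  correct <- stats::runif(2 * n_cells) < 0.7
  prob <- ifelse((truth == "B") == correct, 0.9, 0.1)
  r <- classify_sets(prob, truth, imgs, "B", set_size = 19,
                     n_bootstrap = 1500, seed = 2)
  oracle <- sum(stats::dbinom(10:19, 19, 0.7))
  expect_equal(unname(r["accuracy"]), oracle, tolerance = 0.03)
})

test_that("cross-validated importance ranks the informative feature first", {
  tab <- fake_feature_table(n_per_image = 12, delta = 4, sd = 1, seed = 6,
                            signal_feature = "AvgCurvedness")
  res <- evaluate_l2ogo(tab, model_config("fast-rf"), set_sizes = c(3, 9),
                        n_bootstrap = 50, seed = 3)
  imp <- feature_importance(res)
  expect_equal(imp$feature[1], "AvgCurvedness")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(any(grepl("^(Avg|Min|Max|Var)", imp$feature)))
  expect_true(any(imp$feature %in% c("Volume", "SurfaceArea", "ShapeIndex",
                                     "MeanCurvature", "Curvedness",
                                     "FractalDimension")))
})

test_that("the L2OGO evaluation loop is deterministic given its seed", {
  tab <- fake_feature_table(n_per_image = 8, delta = 2, sd = 1, seed = 10)
  a <- evaluate_l2ogo(tab, model_config("fast-rf", num_trees = 60),
                      set_sizes = c(3, 7), n_bootstrap = 40, seed = 11)
  b <- evaluate_l2ogo(tab, model_config("fast-rf", num_trees = 60),
                      set_sizes = c(3, 7), n_bootstrap = 40, seed = 11)
  expect_equal(a$summary, b$summary)
  expect_equal(a$importance, b$importance)
  expect_equal(a$n_folds, 4)
})
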