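sep <- make_separable_features(60, seed = 1)

test_that("dataset assembly splits and standardizes without leakage", {
  ds <- glyco_dataset(sep$features, sep$labels, seed = 3)
  expect_equal(length(ds$train_idx) + length(ds$test_idx), 360)
  expect_length(intersect(ds$train_idx, ds$test_idx), 0)
  # stratified 80/20
  expect_true(all(table(ds$y[ds$train_idx]) == 48))
  expect_true(all(table(ds$y[ds$test_idx]) == 12))
  # scaler statistics computed on training rows only
  expect_equal(unname(ds$center),
               unname(colMeans(ds$X[ds$train_idx, ])))
  expect_false(isTRUE(all.equal(unname(ds$center), unname(colMeans(ds$X)))))
  thin <- seq(1, 360, by = 12)  # 5 events per class
  expect_error(glyco_dataset(sep$features[thin, ], sep$labels[thin]),
               "stratification")
})

test_that("every model family separates well-separated classes", {
  ds <- glyco_dataset(sep$features, sep$labels, seed = 3)
  bench <- train_bench(ds, seed = 3)
  for (r in bench) {
    expect_gte(r$test_accuracy, 0.99)
    # confusion rows sum to per-class test counts
    expect_equal(unname(rowSums(r$confusion)),
                 unname(as.vector(table(ds$y[ds$test_idx]))))
    # reported accuracy equals trace(confusion)/n_test exactly
    expect_equal(r$test_accuracy,
                 sum(diag(r$confusion)) / length(ds$test_idx))
  }
  # determinism: repeated run gives identical summaries
  expect_identical(summary(bench),
                   summary(train_bench(ds, seed = 3)))
})

test_that("permuted labels score at chance level", {
  set.seed(4)
  ds <- glyco_dataset(sep$features, sample(sep$labels), seed = 4)
  b <- train_bench(ds, seed = 4, families = "MLP", cv_folds = 5)
  # 6 balanced classes: chance 1/6, binomial noise on 72 test events
  expect_lt(abs(b$MLP$test_accuracy - 1 / 6),
            4 * sqrt((1 / 6) * (5 / 6) / 72))
})

test_that("model selection ranks by AUC, then accuracy, then order", {
  rep1 <- structure(list(family = "A", macro_auc = 0.90, test_accuracy = 0.95),
                    class = "model_report")
  rep2 <- structure(list(family = "B", macro_auc = 0.99, test_accuracy = 0.91),
                    class = "model_report")
  expect_equal(select_model(structure(list(rep1, rep2),
                                      class = "glyco_bench"))$family, "B")
  rep3 <- structure(list(family = "C", macro_auc = 0.99, test_accuracy = 0.93),
                    class = "model_report")
  expect_equal(select_model(structure(list(rep2, rep3),
                                      class = "glyco_bench"))$family, "C")
  tie <- structure(list(family = "D", macro_auc = 0.99, test_accuracy = 0.93),
                   class = "model_report")
  expect_equal(select_model(structure(list(rep3, tie),
                                      class = "glyco_bench"))$family, "C")
  expect_equal(select_model(structure(list(rep1), class = "glyco_bench"))$family,
               "A")
})

test_that("permutation importance isolates the informative feature", {
  set.seed(5)
  n <- 120
  # only the blockade ratio carries class information
  feats <- data.frame(sd = rnorm(6 * n), skewness = rnorm(6 * n),
                      duration_ms = 10^rnorm(6 * n, 0.3, 0.2),
                      ratio = rnorm(6 * n, rep(seq(0.1, 0.6, 0.1), each = n),
                                    0.01))
  labs <- rep(c("WT", "Tn", "TF", "STn-1", "STF-1", "MR"), each = n)
  ds <- glyco_dataset(feats, labs, seed = 5)
  b <- train_bench(ds, seed = 5, families = "random_forest", cv_folds = 5)
  imp <- permutation_importance(b$random_forest, ds, n_repeats = 10, seed = 5)
  expect_gte(imp$importance_pct[imp$feature == "ratio"], 90)
  # pure-noise features drop accuracy by ~nothing before normalization
  for (f in c("sd", "skewness"))
    expect_lt(abs(imp$mean_drop[imp$feature == f]), 0.05)
  expect_equal(sum(imp$importance_pct), 100)
  # repeat count changes the Monte-Carlo error, not the estimate
  imp1 <- permutation_importance(b$random_forest, ds, n_repeats = 1, seed = 6)
  imp50 <- permutation_importance(b$random_forest, ds, n_repeats = 50, seed = 6)
  expect_lt(max(abs(imp1$mean_drop - imp50$mean_drop)), 0.1)
})

test_that("learning curve rises to a plateau on separable data", {
  ds <- glyco_dataset(sep$features, sep$labels, seed = 3)
  lc <- learning_curve(ds, sizes = c(36, 36, 144, 288), seed = 3,
                       family = "naive_bayes")
  expect_equal(lc$size, c(36, 144, 288))  # duplicates removed
  expect_gte(lc$cv_accuracy[3], 0.99)
  expect_lte(lc$cv_accuracy[1], lc$cv_accuracy[3] + 0.05)
  expect_error(learning_curve(ds, sizes = 5), "2 events per class")
  expect_error(learning_curve(ds, sizes = 10000), "exceeds")
})

test_that("predict applies the stored scaler to new events", {
  ds <- glyco_dataset(sep$features, sep$labels, seed = 3)
  b <- train_bench(ds, seed = 3, families = "naive_bayes", cv_folds = 5)
  pred <- predict(b$naive_bayes, sep$features)
  expect_gte(mean(as.character(pred) == sep$labels), 0.99)
  pr <- attr(pred, "prob")
  expect_equal(dim(pr), c(360, 6))
  expect_equal(unname(rowSums(pr)), rep(1, 360), tolerance = 1e-6)
})
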