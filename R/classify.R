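#' Model families in the classification bench
#' @export
GLYCO_FAMILIES <- c("SVM", "KNN", "random_forest", "adaboost",
                    "naive_bayes", "gaussian_process", "MLP")

.FEATURE_COLS <- c("sd", "skewness", "duration", "ratio")

# stratified index split: fraction `p` of each class into the first part
.strat_split <- function(y, p, seed) {
  set.seed(seed)
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    k <- round(p * length(idx))
    train <- c(train, sample(idx, k))
  }
  sort(train)
}

# stratified k-fold assignment
.strat_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Assemble a labeled classification dataset
#'
#' Builds the n x 4 feature matrix (`sd`, `skewness`, `duration`, `ratio`),
#' performs a seeded stratified train/test split (default 80/20) and
#' computes standardization statistics on the training rows only -- the
#' test rows never leak into the scaler.
#'
#' @param features data frame with columns `sd`, `skewness`, `duration_ms`
#'   (or `duration`) and `ratio` -- e.g. from [extract_features()] or
#'   [simulate_event_table()].
#' @param labels class labels (character or factor), one per row.
#' @param split training fraction (default 0.8).
#' @param seed RNG seed controlling the split.
#' @return object of class `glyco_dataset`.
#' @export
glyco_dataset <- function(features, labels, split = 0.8, seed = 1L) {
  dur <- if ("duration_ms" %in% names(features)) features$duration_ms
         else features$duration
  X <- cbind(sd = features$sd, skewness = features$skewness,
             duration = dur, ratio = features$ratio)
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  y <- factor(labels)
  stopifnot(nrow(X) == length(y))
  train_idx <- .strat_split(y, split, seed)
  ytr <- y[train_idx]
  if (any(table(ytr) < 10))
    stop("stratification error: every class needs >= 10 training events",
         call. = FALSE)
  center <- colMeans(X[train_idx, , drop = FALSE])
  scl <- apply(X[train_idx, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  structure(list(X = X, y = y, train_idx = train_idx,
                 test_idx = setdiff(seq_len(nrow(X)), train_idx),
                 center = center, scale = scl, seed = as.integer(seed)),
            class = "glyco_dataset")
}

#' @export
print.glyco_dataset <- function(x, ...) {
  cat(sprintf("<glyco_dataset> %d events x %d features, %d classes (%s)\n",
              nrow(x$X), ncol(x$X), nlevels(x$y),
              paste(levels(x$y), collapse = ", ")))
  cat(sprintf("  train %d / test %d (stratified, seed %d)\n",
              length(x$train_idx), length(x$test_idx), x$seed))
  invisible(x)
}

.std <- function(dataset, idx) {
  sweep(sweep(dataset$X[idx, , drop = FALSE], 2, dataset$center),
        2, dataset$scale, "/")
}

# ---- model families ------------------------------------------------------

# multi-class AdaBoost (SAMME) on shallow rpart trees
.fit_samme <- function(X, y, n_rounds = 60, maxdepth = 3) {
  df <- data.frame(X, y = y)
  n <- nrow(df); K <- nlevels(y)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = 0, minsplit = 5,
                                                       xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y))
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break
  }
  structure(list(trees = trees, alphas = alphas, levels = levels(y)),
            class = "samme")
}

.predict_samme <- function(object, X) {
  df <- data.frame(X)
  score <- matrix(0, nrow(df), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (m in seq_along(object$trees)) {
    pred <- stats::predict(object$trees[[m]], df, type = "class")
    score[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      score[cbind(seq_len(nrow(df)), as.integer(pred))] + object$alphas[m]
  }
  p <- score + 1e-9
  p / rowSums(p)
}

.fit_family <- function(family, X, y, seed) {
  set.seed(seed)
  df <- data.frame(X)
  model <- switch(family,
    SVM = e1071::svm(X, y, kernel = "radial", probability = TRUE),
    KNN = caret::knn3(X, y, k = 5),
    random_forest = randomForest::randomForest(X, y, ntree = 300),
    adaboost = .fit_samme(X, y),
    naive_bayes = e1071::naiveBayes(df, y),
    gaussian_process = {
      gp <- NULL
      utils::capture.output(suppressMessages(
        gp <- kernlab::gausspr(X, y, kpar = "automatic")))
      gp
    },
    MLP = nnet::nnet(X, nnet::class.ind(y), size = 64, softmax = TRUE,
                     maxit = 2000, decay = 1e-4, MaxNWts = 10000,
                     trace = FALSE),
    stop("unknown model family: ", family, call. = FALSE)
  )
  list(family = family, model = model, levels = levels(y))
}

.predict_proba <- function(fit, X) {
  lev <- fit$levels
  p <- switch(fit$family,
    SVM = {
      pr <- stats::predict(fit$model, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    KNN = stats::predict(fit$model, X, type = "prob"),
    random_forest = stats::predict(fit$model, X, type = "prob"),
    adaboost = .predict_samme(fit$model, X),
    naive_bayes = stats::predict(fit$model, data.frame(X), type = "raw"),
    gaussian_process = kernlab::predict(fit$model, X, type = "probabilities"),
    MLP = stats::predict(fit$model, X)
  )
  p <- as.matrix(p)
  if (is.null(colnames(p))) colnames(p) <- lev
  p[, lev, drop = FALSE]
}

# hard class prediction; the Gaussian process uses its response output
# (its one-vs-all probability coupling is poorly calibrated, while the
# response labels are exact), all other families take the argmax of the
# class probabilities
.predict_class <- function(fit, X) {
  if (fit$family == "gaussian_process") {
    as.character(kernlab::predict(fit$model, X))
  } else {
    p <- .predict_proba(fit, X)
    colnames(p)[max.col(p, ties.method = "first")]
  }
}

# rank-based one-vs-rest AUC, macro averaged; plus average precision
.binary_auc <- function(truth, score) {
  as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                 levels = c(FALSE, TRUE), direction = "<")))
}

.avg_precision <- function(truth, score) {
  o <- order(score, decreasing = TRUE)
  t <- truth[o]
  prec <- cumsum(t) / seq_along(t)
  sum(prec[t]) / sum(t)
}

.class_metrics <- function(y, prob) {
  lev <- levels(y)
  auc <- ap <- stats::setNames(numeric(length(lev)), lev)
  for (l in lev) {
    truth <- y == l
    auc[l] <- .binary_auc(truth, prob[, l])
    ap[l] <- .avg_precision(truth, prob[, l])
  }
  list(auc = auc, ap = ap)
}

# ---- bench ---------------------------------------------------------------

#' Train the multi-model classification bench
#'
#' Trains each model family on the standardized training set with
#' stratified 10-fold cross-validation, then evaluates once on the held-out
#' test rows: test accuracy, per-class and macro one-vs-rest AUC, average
#' precision, and the confusion matrix. All randomness (folds, model
#' initialization) derives from `seed`, so a repeated call reproduces the
#' reports exactly.
#'
#' @param dataset a [glyco_dataset()].
#' @param seed RNG seed (default: the dataset's).
#' @param families subset of [GLYCO_FAMILIES].
#' @param cv_folds number of CV folds (default 10).
#' @return object of class `glyco_bench`: a list of `model_report`s, one
#'   per family, each carrying `cv_accuracy`, `test_accuracy`, `macro_auc`,
#'   `auc_per_class`, `ap_per_class`, `confusion`, the fitted model, and
#'   the standardizer needed by [predict.model_report()].
#' @export
train_bench <- function(dataset, seed = dataset$seed,
                        families = GLYCO_FAMILIES, cv_folds = 10) {
  stopifnot(inherits(dataset, "glyco_dataset"))
  ytr <- dataset$y[dataset$train_idx]
  yte <- dataset$y[dataset$test_idx]
  if (any(table(ytr) < cv_folds))
    stop("stratification error: every class needs >= ", cv_folds,
         " training events for ", cv_folds, "-fold CV", call. = FALSE)
  Xtr <- .std(dataset, dataset$train_idx)
  Xte <- .std(dataset, dataset$test_idx)
  fold <- .strat_folds(ytr, cv_folds, seed)
  reports <- lapply(seq_along(families), function(fi) {
    fam <- families[fi]
    fam_seed <- seed + 1000L * fi
    cv_acc <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      fit <- .fit_family(fam, Xtr[tr, , drop = FALSE], droplevels(ytr[tr]),
                         fam_seed + f)
      mean(.predict_class(fit, Xtr[!tr, , drop = FALSE]) ==
             as.character(ytr[!tr]))
    }, numeric(1))
    fit <- .fit_family(fam, Xtr, ytr, fam_seed)
    p <- .predict_proba(fit, Xte)
    pred <- factor(.predict_class(fit, Xte), levels = levels(yte))
    cm <- table(truth = yte, predicted = pred)
    metrics <- .class_metrics(yte, p)
    structure(list(
      family = fam, cv_accuracy = mean(cv_acc), cv_fold_accuracy = cv_acc,
      test_accuracy = mean(pred == yte), macro_auc = mean(metrics$auc),
      auc_per_class = metrics$auc, ap_per_class = metrics$ap,
      confusion = cm, prob_test = p, fit = fit,
      center = dataset$center, scale = dataset$scale
    ), class = "model_report")
  })
  names(reports) <- families
  structure(reports, class = "glyco_bench")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s: CV acc %.3f, test acc %.3f, macro AUC %.4f\n",
              x$family, x$cv_accuracy, x$test_accuracy, x$macro_auc))
  invisible(x)
}

#' @export
print.glyco_bench <- function(x, ...) {
  cat("<glyco_bench>\n")
  for (r in x)
    cat(sprintf("  %-16s CV acc %.3f  test acc %.3f  macro AUC %.4f\n",
                r$family, r$cv_accuracy, r$test_accuracy, r$macro_auc))
  invisible(x)
}

#' @export
summary.glyco_bench <- function(object, ...) {
  data.frame(family = vapply(object, `[[`, character(1), "family"),
             cv_accuracy = vapply(object, `[[`, numeric(1), "cv_accuracy"),
             test_accuracy = vapply(object, `[[`, numeric(1), "test_accuracy"),
             macro_auc = vapply(object, `[[`, numeric(1), "macro_auc"),
             row.names = NULL)
}

#' Predict class labels for new events
#'
#' Applies the report's training standardizer and model to a new feature
#' table.
#'
#' @param object a `model_report` (typically from [select_model()]).
#' @param newdata data frame with `sd`, `skewness`, `duration_ms` (or
#'   `duration`) and `ratio` columns.
#' @param ... unused.
#' @return factor of predicted labels with a `"prob"` attribute (the class
#'   probability matrix).
#' @export
predict.model_report <- function(object, newdata, ...) {
  dur <- if ("duration_ms" %in% names(newdata)) newdata$duration_ms
         else newdata$duration
  X <- cbind(sd = newdata$sd, skewness = newdata$skewness,
             duration = dur, ratio = newdata$ratio)
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  pred <- factor(.predict_class(object$fit, X), levels = object$fit$levels)
  attr(pred, "prob") <- .predict_proba(object$fit, X)
  pred
}

#' Select the best model from a bench
#'
#' Highest macro AUC wins; ties are broken by test accuracy, then by the
#' fixed family order of [GLYCO_FAMILIES].
#'
#' @param bench a `glyco_bench`.
#' @return the winning `model_report`.
#' @export
select_model <- function(bench) {
  stopifnot(length(bench) >= 1)
  auc <- vapply(bench, `[[`, numeric(1), "macro_auc")
  acc <- vapply(bench, `[[`, numeric(1), "test_accuracy")
  bench[[order(-auc, -acc, seq_along(bench))[1]]]
}

#' Permutation feature importance
#'
#' For each feature, measures the mean drop in test accuracy over
#' `n_repeats` random permutations of that feature's values in the test
#' set. The per-feature drops (floored at zero) are normalized to
#' percentages summing to 100.
#'
#' @param report a `model_report`.
#' @param dataset the [glyco_dataset()] the bench was trained on.
#' @param n_repeats permutations per feature (default 20).
#' @param seed RNG seed.
#' @return data frame with `feature`, `mean_drop` (raw accuracy drop) and
#'   `importance_pct`.
#' @export
permutation_importance <- function(report, dataset, n_repeats = 20,
                                   seed = dataset$seed) {
  Xte <- .std(dataset, dataset$test_idx)
  yte <- dataset$y[dataset$test_idx]
  acc <- function(X) mean(.predict_class(report$fit, X) == as.character(yte))
  base <- acc(Xte)
  set.seed(seed)
  drops <- vapply(colnames(Xte), function(feat) {
    mean(vapply(seq_len(n_repeats), function(r) {
      Xp <- Xte
      Xp[, feat] <- sample(Xp[, feat])
      base - acc(Xp)
    }, numeric(1)))
  }, numeric(1))
  pos <- pmax(drops, 0)
  pct <- if (sum(pos) > 0) 100 * pos / sum(pos)
         else rep(100 / length(pos), length(pos))
  data.frame(feature = colnames(Xte), mean_drop = unname(drops),
             importance_pct = unname(pct), row.names = NULL)
}

#' Learning curve of one model family
#'
#' Cross-validated accuracy at increasing training-set sizes (stratified
#' subsamples of the training rows). Duplicate sizes are removed.
#'
#' @param dataset a [glyco_dataset()].
#' @param sizes training sizes to evaluate.
#' @param seed RNG seed.
#' @param family model family (default `"MLP"`).
#' @param cv_folds folds per size (capped by the smallest class count).
#' @return data frame with `size` and `cv_accuracy`.
#' @export
learning_curve <- function(dataset, sizes, seed = dataset$seed,
                           family = "MLP", cv_folds = 10) {
  sizes <- sort(unique(round(sizes)))
  ytr_all <- dataset$y[dataset$train_idx]
  if (any(sizes > length(dataset$train_idx)))
    stop("size exceeds available training rows", call. = FALSE)
  if (any(sizes < 2 * nlevels(ytr_all)))
    stop("sizes must allow >= 2 events per class", call. = FALSE)
  Xtr_all <- .std(dataset, dataset$train_idx)
  acc <- vapply(seq_along(sizes), function(si) {
    sz <- sizes[si]
    set.seed(seed + si)
    sel <- .strat_split(ytr_all, sz / length(ytr_all), seed + si)
    y <- droplevels(ytr_all[sel])
    X <- Xtr_all[sel, , drop = FALSE]
    k <- max(2, min(cv_folds, min(table(y))))
    fold <- .strat_folds(y, k, seed + si)
    mean(vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- .fit_family(family, X[tr, , drop = FALSE], droplevels(y[tr]),
                         seed + si * 100 + f)
      mean(.predict_class(fit, X[!tr, , drop = FALSE]) ==
             as.character(y[!tr]))
    }, numeric(1)))
  }, numeric(1))
  data.frame(size = sizes, cv_accuracy = acc)
}
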