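CLASSIFIER_FAMILIES <- c("random_forest", "gradient_boosting",
                         "k_nearest_neighbors", "logistic_regression",
                         "support_vector_machine", "decision_tree")
TREE_FAMILIES <- c("random_forest", "gradient_boosting", "decision_tree")
CLASS_LEVELS <- c("non_responder", "responder")

#' Label responders from motor-score change
#'
#' Computes the relative UPDRS-III improvement
#' `delta = (baseline - follow-up) / baseline * 100` and labels subjects
#' whose improvement reaches the clinically meaningful boundary
#' (inclusive, default 15%) as responders.
#'
#' @param clinical data.frame with `subject_id`, `updrs_bl`, `updrs_fu`.
#' @param threshold_percent responder boundary (default 15).
#' @return the table with added `delta_percent` and `responder` columns.
#' @export
label_responders <- function(clinical, threshold_percent = 15) {
  need <- c("subject_id", "updrs_bl", "updrs_fu")
  if (!all(need %in% names(clinical))) {
    stop_brainfp("clinical table needs columns: %s", paste(need, collapse = ", "))
  }
  bad <- clinical$updrs_bl <= 0
  if (any(bad)) {
    stop_brainfp("non-positive baseline score for subject(s): %s",
                 paste(clinical$subject_id[bad], collapse = ", "))
  }
  clinical$delta_percent <-
    (clinical$updrs_bl - clinical$updrs_fu) / clinical$updrs_bl * 100
  clinical$responder <- clinical$delta_percent >= threshold_percent
  clinical
}

#' Classifier specification
#'
#' Bundles a model family, its hyperparameter grid for the inner
#' cross-validated grid search, the inner fold count, and the seed.
#' Default grids are small standard ones; the inner selection score is
#' accuracy.
#'
#' @param family one of `"random_forest"`, `"gradient_boosting"`,
#'   `"k_nearest_neighbors"`, `"logistic_regression"`,
#'   `"support_vector_machine"`, `"decision_tree"`.
#' @param grid data.frame of hyperparameter combinations (defaults per
#'   family).
#' @param inner_folds inner CV folds (default 5).
#' @param seed RNG seed controlling fold assignment and stochastic
#'   learners.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = "random_forest", grid = NULL,
                       inner_folds = 5, seed = 1) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  if (is.null(grid)) {
    grid <- switch(family,
      random_forest = expand.grid(ntree = c(100, 300),
                                  max_depth = c(0, 3, 5)),
      gradient_boosting = expand.grid(eta = c(0.05, 0.1),
                                      nrounds = c(100, 300),
                                      max_depth = c(2, 3)),
      k_nearest_neighbors = expand.grid(
        k = c(3, 5, 7), weights = c("uniform", "distance"),
        stringsAsFactors = FALSE),
      logistic_regression = data.frame(intercept_only = FALSE),
      support_vector_machine = expand.grid(cost = c(0.5, 1, 2)),
      decision_tree = expand.grid(maxdepth = c(2, 3, 4))
    )
  }
  if (nrow(grid) < 1) stop_brainfp("hyperparameter grid must be nonempty")
  if (inner_folds < 2) stop_brainfp("inner_folds must be >= 2")
  structure(list(family = family, grid = grid,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

# distance-based kNN score: weighted fraction of responder neighbours
knn_score <- function(x_train, y_train, x_test, k, weights = "uniform") {
  pos <- y_train == CLASS_LEVELS[2]
  apply(x_test, 1, function(p) {
    d <- sqrt(colSums((t(x_train) - p)^2))
    nb <- order(d, seq_along(d))[seq_len(min(k, length(d)))]
    w <- if (weights == "distance") 1 / pmax(d[nb], 1e-10) else rep(1, length(nb))
    sum(w * pos[nb]) / sum(w)
  })
}

# fit one model family on standardized training data and score test rows;
# returns list(score = P(responder), importance = named vector or NULL)
fit_and_score <- function(family, params, x_train, y_train, x_test, seed) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  switch(family,
    random_forest = {
      max_nodes <- if (params$max_depth > 0) {
        min(2^params$max_depth, nrow(x_train))
      } else {
        NULL
      }
      fit <- with_seed(seed, randomForest::randomForest(
        x = x_train, y = y_train,
        ntree = params$ntree, maxnodes = max_nodes))
      list(score = stats::predict(fit, x_test, type = "prob")[, CLASS_LEVELS[2]],
           importance = fit$importance[, "MeanDecreaseGini"])
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(x_train,
                                     label = as.numeric(y_train) - 1)
      fit <- with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = params$eta,
                      max_depth = params$max_depth, nthread = 1,
                      seed = seed),
        data = dtrain, nrounds = params$nrounds))
      imp <- xgboost::xgb.importance(model = fit)
      iv <- stats::setNames(rep(0, ncol(x_train)), colnames(x_train))
      if (!is.null(imp) && nrow(imp) > 0) {
        known <- imp$Feature %in% names(iv)
        iv[imp$Feature[known]] <- imp$Gain[known]
      }
      list(score = stats::predict(fit, xgboost::xgb.DMatrix(x_test)),
           importance = iv)
    },
    k_nearest_neighbors = {
      list(score = knn_score(x_train, y_train, x_test,
                             k = params$k, weights = params$weights),
           importance = NULL)
    },
    logistic_regression = {
      df <- data.frame(x_train, y = y_train, check.names = FALSE)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      list(score = suppressWarnings(
             stats::predict(fit, data.frame(x_test, check.names = FALSE),
                            type = "response")),
           importance = NULL)
    },
    support_vector_machine = {
      fit <- with_seed(seed, e1071::svm(x_train, y_train, kernel = "radial",
                                        cost = params$cost, scale = FALSE))
      pr <- stats::predict(fit, x_test, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      lab <- colnames(attr(pr, "decision.values"))
      # decision value > 0 favours the first class in the column label
      score <- if (startsWith(lab, CLASS_LEVELS[2])) stats::plogis(dv)
               else stats::plogis(-dv)
      list(score = score, importance = NULL)
    },
    decision_tree = {
      df <- data.frame(x_train, y = y_train, check.names = FALSE)
      fit <- with_seed(seed, rpart::rpart(
        y ~ ., data = df, method = "class",
        control = rpart::rpart.control(maxdepth = params$maxdepth,
                                       minsplit = 4, cp = 0.001)))
      iv <- stats::setNames(rep(0, ncol(x_train)), colnames(x_train))
      vi <- fit$variable.importance
      if (!is.null(vi)) iv[names(vi)] <- vi
      score <- stats::predict(fit, data.frame(x_test, check.names = FALSE),
                              type = "prob")[, CLASS_LEVELS[2]]
      list(score = score, importance = iv)
    }
  )
}

# stratified fold assignment
make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  function(newx) sweep(sweep(as.matrix(newx), 2, mu, "-"), 2, sd, "/")
}

# inner grid search by k-fold CV accuracy; returns best grid row index
tune_grid <- function(x, y, spec, seed) {
  if (nrow(spec$grid) == 1) return(1L)
  k <- spec$inner_folds
  min_class <- min(table(y))
  if (min_class < k) {
    message(sprintf("inner folds reduced from %d to %d (smallest class has %d)",
                    k, max(2L, min_class), min_class))
    k <- max(2L, min_class)
  }
  fold <- make_folds(y, k, seed)
  acc <- vapply(seq_len(nrow(spec$grid)), function(g) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      std <- standardizer(x[tr, , drop = FALSE])
      sc <- fit_and_score(spec$family, spec$grid[g, , drop = FALSE],
                          std(x[tr, , drop = FALSE]), y[tr],
                          std(x[!tr, , drop = FALSE]),
                          seed = derive_seed(seed, g * 131L + f))
      correct <- correct + sum((sc$score > 0.5) == (y[!tr] == CLASS_LEVELS[2]))
    }
    correct / length(y)
  }, numeric(1))
  which.max(acc)
}

as_class_factor <- function(labels) {
  if (is.logical(labels)) {
    factor(ifelse(labels, CLASS_LEVELS[2], CLASS_LEVELS[1]), levels = CLASS_LEVELS)
  } else if (is.factor(labels) || is.character(labels)) {
    f <- factor(as.character(labels), levels = CLASS_LEVELS)
    if (anyNA(f)) stop_brainfp("labels must be logical or use levels %s",
                               paste(CLASS_LEVELS, collapse = "/"))
    f
  } else {
    stop_brainfp("labels must be logical or factor")
  }
}

# rank-based ROC-AUC used as internal fallback-free PR companion
average_precision <- function(truth, score) {
  ord <- order(-score, seq_along(score))
  y <- truth[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  d_rec <- diff(c(0, rec))
  sum(prec * d_rec)
}

#' Nested leave-one-out cross-validated classification
#'
#' Runs the full unbiased evaluation scheme: each subject is held out
#' once; within each training set, features are standardized using
#' training-set parameters only and hyperparameters are selected by a
#' stratified inner k-fold grid search (accuracy score); the tuned model
#' predicts the held-out subject. Classification metrics are computed on
#' the pooled held-out predictions (single-sample folds make per-fold
#' AUC undefined), and mean-decrease-in-impurity importances are averaged
#' over outer folds for tree-based families.
#'
#' @param features subjects x features data.frame or matrix.
#' @param labels logical (TRUE = responder) or factor with levels
#'   `non_responder`/`responder`.
#' @param spec a [model_spec()].
#' @return object of class `cv_report`: `per_fold_predictions`
#'   (data.frame with subject, truth, score, predicted), `metrics`
#'   (accuracy, precision, recall, f1, roc_auc, pr_auc),
#'   `confusion_matrix` (fold-averaged proportions), `importances`
#'   (or `NULL`), `family`, `seed`.
#' @export
nested_loocv_classify <- function(features, labels, spec = model_spec()) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as_class_factor(labels)
  n <- nrow(x)
  if (n < 6) stop_brainfp("need at least 6 subjects, got %d", n)
  if (length(unique(y)) < 2) stop_brainfp("both classes must be present")
  if (anyNA(x)) stop_brainfp("features contain missing values")

  score <- numeric(n)
  imp_acc <- NULL
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    y_tr <- y[tr]
    if (length(unique(y_tr)) < 2) {
      stop_brainfp("training fold %d contains a single class", i)
    }
    std <- standardizer(x[tr, , drop = FALSE])
    best <- tune_grid(x[tr, , drop = FALSE], y_tr, spec,
                      seed = derive_seed(spec$seed, i))
    fit <- fit_and_score(spec$family, spec$grid[best, , drop = FALSE],
                         std(x[tr, , drop = FALSE]), y_tr,
                         std(x[i, , drop = FALSE]),
                         seed = derive_seed(spec$seed, 100000L + i))
    score[i] <- fit$score
    if (!is.null(fit$importance)) {
      imp_acc <- rbind(imp_acc, fit$importance)
    }
  }
  predicted <- factor(ifelse(score > 0.5, CLASS_LEVELS[2], CLASS_LEVELS[1]),
                      levels = CLASS_LEVELS)
  truth_pos <- y == CLASS_LEVELS[2]
  tp <- sum(predicted == CLASS_LEVELS[2] & truth_pos)
  fp <- sum(predicted == CLASS_LEVELS[2] & !truth_pos)
  fn <- sum(predicted == CLASS_LEVELS[1] & truth_pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  roc_auc <- as.numeric(pROC::auc(response = y, predictor = score,
                                  levels = CLASS_LEVELS, direction = "<",
                                  quiet = TRUE))
  metrics <- c(accuracy = mean(predicted == y),
               precision = precision, recall = recall, f1 = f1,
               roc_auc = roc_auc,
               pr_auc = average_precision(truth_pos, score))
  importances <- if (!is.null(imp_acc)) colMeans(imp_acc) else NULL
  structure(
    list(per_fold_predictions = data.frame(
           subject = rownames(x) %||% as.character(seq_len(n)),
           truth = y, score = score, predicted = predicted),
         metrics = metrics,
         confusion_matrix = table(truth = y, predicted = predicted) / n,
         importances = importances,
         family = spec$family, seed = spec$seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d held-out predictions\n", x$family,
              nrow(x$per_fold_predictions)))
  print(round(x$metrics, 3))
  invisible(x)
}

#' Permutation significance of classification performance
#'
#' Repeats the entire nested LOOCV pipeline under random permutations of
#' the class labels (features untouched), building empirical null
#' distributions for accuracy, ROC-AUC and PR-AUC. One-sided p-values
#' (`(1 + #\{null >= observed\}) / (n_perm + 1)`) are Benjamini-Hochberg
#' adjusted across the three metrics.
#'
#' @param features,labels,spec as in [nested_loocv_classify()].
#' @param n_perm label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return object of class `permutation_significance`: `observed`
#'   (the `cv_report`), `null` (n_perm x 3 matrix), `p_raw`, `p_adj`,
#'   `n_perm`, `seed`.
#' @export
permutation_significance <- function(features, labels, spec = model_spec(),
                                     n_perm = 1000, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100: permutation p-values will be coarse")
  observed <- nested_loocv_classify(features, labels, spec)
  y <- as_class_factor(labels)
  mets <- c("accuracy", "roc_auc", "pr_auc")
  null_mat <- matrix(NA_real_, n_perm, length(mets),
                     dimnames = list(NULL, mets))
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample(seq_along(y)))
  })
  for (i in seq_len(n_perm)) {
    rep_i <- nested_loocv_classify(features, y[perms[[i]]], spec)
    null_mat[i, ] <- rep_i$metrics[mets]
  }
  p_raw <- vapply(mets, function(m) {
    (1 + sum(null_mat[, m] >= observed$metrics[[m]])) / (n_perm + 1)
  }, numeric(1))
  structure(
    list(observed = observed, null = null_mat,
         p_raw = p_raw, p_adj = bh_adjust(p_raw),
         n_perm = n_perm, seed = seed),
    class = "permutation_significance"
  )
}

#' @export
print.permutation_significance <- function(x, ...) {
  cat(sprintf("<permutation_significance> %d permutations\n", x$n_perm))
  print(data.frame(observed = round(x$observed$metrics[names(x$p_raw)], 3),
                   p_raw = round(x$p_raw, 4), p_adj = round(x$p_adj, 4)))
  invisible(x)
}

#' Ranked feature-importance summary
#'
#' Normalizes the fold-averaged mean-decrease-in-impurity importances of
#' a tree-based classifier to sum to one and ranks features descending
#' (ties broken alphabetically by feature name).
#'
#' @param report a `cv_report` from a tree-based family.
#' @return data.frame with `feature`, `importance`, `rank`.
#' @export
feature_importance_summary <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  if (!report$family %in% TREE_FAMILIES) {
    stop_brainfp("importance undefined for family '%s'", report$family)
  }
  imp <- report$importances
  if (is.null(imp)) stop_brainfp("report carries no importances")
  share <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  ord <- order(-share, names(share))
  data.frame(feature = names(share)[ord],
             importance = unname(share[ord]),
             rank = seq_along(share),
             row.names = NULL)
}
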