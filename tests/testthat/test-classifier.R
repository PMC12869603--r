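sep_features <- function(n = 23, n_pos = 13, shift = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), c(n_pos, n - n_pos))
  x <- matrix(rnorm(n * 8), n, 8)
  colnames(x) <- c("strength", "eigcent", "cpl", "mfpt", "modularity",
                   "participation", "assortativity", "richclub")
  x[y, 1] <- x[y, 1] + shift
  list(x = x, y = y)
}

test_that("responder labeling follows the inclusive percent-change rule", {
  clin <- label_responders(data.frame(
    subject_id = c("a", "b", "c"),
    updrs_bl = c(40, 30, 37.8),
    updrs_fu = c(34, 30, 32.5)))
  expect_equal(clin$delta_percent, c(15, 0, (37.8 - 32.5) / 37.8 * 100),
               tolerance = 1e-12)
  expect_equal(clin$responder, c(TRUE, FALSE, FALSE))
  expect_lt(clin$delta_percent[3], 15)  # 14.02: just under the boundary
  expect_error(label_responders(data.frame(subject_id = "z", updrs_bl = 0,
                                           updrs_fu = 1)), "z")
  # raising the threshold never adds responders
  set.seed(2)
  tab <- data.frame(subject_id = sprintf("s%d", 1:30),
                    updrs_bl = runif(30, 20, 60), updrs_fu = runif(30, 10, 60))
  counts <- vapply(c(5, 15, 25, 40), function(th) {
    sum(label_responders(tab, th)$responder)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("nested LOOCV holds each subject out exactly once, without leakage", {
  d <- sep_features(n = 12, n_pos = 6)
  rep <- nested_loocv_classify(d$x, d$y, fast_knn_spec(seed = 5))
  expect_equal(nrow(rep$per_fold_predictions), 12)
  expect_equal(sort(rep$per_fold_predictions$subject),
               sort(as.character(1:12)))
  expect_equal(sum(rep$confusion_matrix), 1)
  # determinism
  rep2 <- nested_loocv_classify(d$x, d$y, fast_knn_spec(seed = 5))
  expect_identical(rep$per_fold_predictions$score,
                   rep2$per_fold_predictions$score)
  # leak detection: an oracle LOOCV that standardizes per training fold
  # must match the implementation, while a variant that leaks the
  # held-out subject into the scaling differs on a crafted dataset with
  # one extreme subject
  x_leak <- d$x
  x_leak[1, ] <- x_leak[1, ] + 50
  knn5 <- function(xtr, ytr, xte) {
    dist <- sqrt(colSums((t(xtr) - xte)^2))
    nb <- order(dist, seq_along(dist))[1:5]
    mean(ytr[nb])
  }
  loocv_scores <- function(x, y, leak) {
    vapply(seq_len(nrow(x)), function(i) {
      ref <- if (leak) x else x[-i, , drop = FALSE]
      mu <- colMeans(ref)
      sd <- apply(ref, 2, stats::sd); sd[sd == 0] <- 1
      z <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
      knn5(z[-i, , drop = FALSE], y[-i], z[i, ])
    }, numeric(1))
  }
  rep_contract <- nested_loocv_classify(x_leak, d$y, fast_knn_spec(seed = 5))
  oracle <- loocv_scores(x_leak, d$y, leak = FALSE)
  leaky <- loocv_scores(x_leak, d$y, leak = TRUE)
  expect_equal(rep_contract$per_fold_predictions$score, oracle,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(oracle, leaky)))
})

test_that("well-separated classes are classified perfectly", {
  d <- sep_features(shift = 6, seed = 3)
  rep <- suppressMessages(
    nested_loocv_classify(d$x, d$y, model_spec("random_forest", seed = 3)))
  expect_equal(rep$metrics[["accuracy"]], 1.0)
  expect_equal(rep$metrics[["roc_auc"]], 1.0)
  expect_equal(rep$metrics[["pr_auc"]], 1.0)
})

test_that("every model family produces valid pooled metrics", {
  d <- sep_features(n = 14, n_pos = 7, shift = 5, seed = 4)
  fams <- c("random_forest", "gradient_boosting", "k_nearest_neighbors",
            "logistic_regression", "support_vector_machine", "decision_tree")
  for (fam in fams) {
    spec <- model_spec(fam, seed = 4)
    rep <- suppressMessages(nested_loocv_classify(d$x, d$y, spec))
    expect_true(all(rep$metrics >= 0 & rep$metrics <= 1),
                info = fam)
    expect_gt(rep$metrics[["roc_auc"]], 0.5)
  }
})

test_that("shuffled labels keep pooled accuracy near the majority share", {
  accs <- vapply(1:10, function(seed) {
    set.seed(seed + 400)
    d <- sep_features(n = 20, n_pos = 10, shift = 0, seed = seed + 400)
    rep <- nested_loocv_classify(d$x, sample(d$y), fast_knn_spec(seed = seed))
    rep$metrics[["accuracy"]]
  }, numeric(1))
  # majority share is 0.5; binomial noise at n = 20 over 10 runs
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("input contracts are enforced", {
  d <- sep_features(n = 8, n_pos = 4)
  expect_error(nested_loocv_classify(d$x[1:4, ], d$y[1:4], fast_knn_spec()),
               "at least 6")
  expect_error(nested_loocv_classify(d$x, rep(TRUE, 8), fast_knn_spec()),
               "both classes")
  expect_error(nested_loocv_classify(d$x, d$y,
                                     model_spec("random_forest",
                                                grid = data.frame()[0, ])),
               "grid|undefined|nonempty")
  expect_error(model_spec("naive_bayes"), "arg")
})

test_that("permutation significance is one-sided and BH-corrected over three metrics", {
  d <- sep_features(n = 16, n_pos = 8, shift = 5, seed = 6)
  sig <- suppressWarnings(permutation_significance(
    d$x, d$y, fast_knn_spec(seed = 6), n_perm = 180, seed = 7))
  expect_equal(names(sig$p_raw), c("accuracy", "roc_auc", "pr_auc"))
  expect_equal(sig$p_adj, bh_adjust(sig$p_raw), ignore_attr = TRUE)
  expect_true(all(sig$p_adj < 0.05))
  # a metric below the null median must yield p above one half
  d0 <- sep_features(n = 16, n_pos = 8, shift = 0, seed = 8)
  sig0 <- suppressWarnings(permutation_significance(
    d0$x, d0$y, fast_knn_spec(seed = 8), n_perm = 60, seed = 9))
  below <- sig0$observed$metrics[c("accuracy", "roc_auc", "pr_auc")] <
    apply(sig0$null, 2, stats::median)
  expect_true(all(sig0$p_raw[below] > 0.5))
})

test_that("feature importance is normalized, ranked, and tree-only", {
  d <- sep_features(shift = 6, seed = 3)
  rep_gb <- suppressMessages(
    nested_loocv_classify(d$x, d$y, model_spec("gradient_boosting", seed = 3)))
  imp <- feature_importance_summary(rep_gb)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_equal(imp$feature[1], "strength")
  expect_gt(imp$importance[1], 0.5)
  rep_rf <- suppressMessages(
    nested_loocv_classify(d$x, d$y, model_spec("random_forest", seed = 3)))
  expect_equal(feature_importance_summary(rep_rf)$feature[1], "strength")
  rep_knn <- nested_loocv_classify(d$x, d$y, fast_knn_spec(seed = 3))
  expect_error(feature_importance_summary(rep_knn), "importance undefined")
})

test_that("pure-noise features spread importance nearly uniformly", {
  spreads <- vapply(1:3, function(seed) {
    set.seed(seed + 600)
    x <- matrix(rnorm(23 * 8), 23, 8)
    colnames(x) <- paste0("f", 1:8)
    y <- rep(c(TRUE, FALSE), c(13, 10))
    rep <- nested_loocv_classify(
      x, y, model_spec("random_forest",
                       grid = data.frame(ntree = 300, max_depth = 0),
                       seed = seed))
    imp <- feature_importance_summary(rep)
    max(imp$importance) - min(imp$importance)
  }, numeric(1))
  expect_true(all(spreads < 0.2))
})

test_that("features from the opposite-direction mask carry no predictive signal", {
  run <- recovery_run(1, both_directions = TRUE)
  clin <- generate_clinical_outcomes(run$cohort)
  predict_with <- function(mask) {
    feats <- patient_mask_features(run$cohort, mask)
    y <- clin$responder[match(rownames(feats), clin$subject_id)]
    rep <- suppressMessages(
      nested_loocv_classify(feats, y, model_spec("random_forest", seed = 1)))
    rep$metrics[["roc_auc"]]
  }
  auc_fw <- predict_with(run$masks$a_gt_b)
  auc_rev <- predict_with(run$masks$b_gt_a)
  expect_gt(run$masks$b_gt_a$n_edges, 0)
  expect_lt(auc_rev, 0.65)
  expect_gt(auc_fw - auc_rev, 0.15)
})
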