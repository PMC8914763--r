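make_ds <- function(X, y) labeled_dataset(X, y)

test_that("1-NN assigns the class of the nearest training vector", {
  cfg <- pipeline_config(standardize_features = FALSE)
  X <- rbind(rep(0, 8), rep(1, 8), rep(3, 8))
  ds <- make_ds(X, c(0L, 1L, 1L))
  self <- knn_classify(X[1, ], ds, cfg)
  expect_equal(self$label, 0L)
  expect_equal(self$distance, 0)

  near <- knn_classify(rep(0.9, 8), ds, cfg)   # distances ~2.5 vs ~0.28
  expect_equal(near$label, 1L)
  expect_gt(near$score, 0)                     # positive = T-leaning

  expect_error(knn_classify(X[1, ], make_ds(X, c(0L, 0L, 0L)), cfg),
               "both classes")
})

test_that("1-NN labels equal the exhaustive minimum-distance oracle", {
  cfg <- pipeline_config(standardize_features = FALSE)
  set.seed(13)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    X <- matrix(round(rnorm(n * 8), 2), n, 8)
    if (i %% 3 == 0) X[2, ] <- X[1, ]  # exercise distance ties
    y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    ds <- make_ds(X, y)
    test_vec <- round(rnorm(8), 2)
    if (i %% 3 == 0) test_vec <- X[1, ]  # tied at distance 0
    got <- knn_classify(test_vec, ds, cfg)
    expect_identical(got$label, brute_nn_label(test_vec, X, y))
  }
})

test_that("standardization uses training statistics and changes the metric", {
  set.seed(14)
  X <- cbind(matrix(rnorm(20 * 7, 0, 0.01), 20, 7), c(rep(0, 10), rep(50, 10)))
  y <- rep(c(0L, 1L), each = 10)
  ds <- make_ds(X, y)
  raw <- knn_classify(c(rnorm(7, 0, 0.01), 26), ds,
                      pipeline_config(standardize_features = FALSE))
  # with raw distances the huge 8th feature dominates
  expect_equal(raw$label, 1L)
  std <- knn_classify(c(rnorm(7, 0, 0.01), 26), ds, pipeline_config())
  expect_true(std$label %in% c(0L, 1L))  # defined either way
  # zero-variance features must not produce NaN distances
  Xc <- X; Xc[, 3] <- 7
  stdc <- knn_classify(c(rep(7, 7), 26), make_ds(Xc, y), pipeline_config())
  expect_true(is.finite(stdc$distance))
})

test_that("confusion metrics compute the three diagnostic ratios", {
  m <- confusion_metrics(list(tp = 17, tn = 18, fp = 2, fn = 3))
  expect_equal(unname(m), c(0.85, 0.90, 0.875))
  expect_equal(unname(confusion_metrics(list(tp = 5, tn = 7, fp = 0, fn = 0))),
               c(1, 1, 1))
  expect_error(confusion_metrics(list(tp = 0, tn = 5, fp = 1, fn = 0)),
               "sensitivity")
  expect_error(confusion_metrics(list(tp = 2, tn = 0, fp = 0, fn = 1)),
               "specificity")
})

test_that("accuracy decomposes into prevalence-weighted sensitivity/specificity", {
  set.seed(15)
  for (i in 1:50) {
    cm <- list(tp = sample(1:30, 1), tn = sample(1:30, 1),
               fp = sample(0:30, 1), fn = sample(0:30, 1))
    m <- confusion_metrics(cm)
    P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("ROC handles separation, ties and random scores correctly", {
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_curve(rep(0.3, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")

  set.seed(16)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    sc <- round(rnorm(n), 1)  # rounding forces frequent ties
    lb <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    r <- roc_curve(sc, lb)
    expect_equal(r$auc, brute_auc(sc, lb), tolerance = 1e-12)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
    expect_equal(unlist(r$roc_points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]),
                 c(fpr = 1, tpr = 1))
    # invariant under strictly increasing score transforms
    expect_equal(roc_curve(exp(sc), lb)$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("ROC and AUC agree with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:10) {
    sc <- rnorm(30)
    lb <- c(0L, 1L, sample(0:1, 28, replace = TRUE))
    want <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                           direction = "<")))
    expect_equal(roc_curve(sc, lb)$auc, want, tolerance = 1e-12)
  }
})

test_that("repeated-split evaluation separates well-separated classes", {
  set.seed(18)
  X <- rbind(matrix(rnorm(15 * 8, 0, 0.1), 15, 8),
             matrix(rnorm(15 * 8, 10, 0.1), 15, 8))
  ds <- make_ds(X, rep(c(0L, 1L), each = 15))
  cfg <- pipeline_config(n_train_per_class = 8, n_repeats = 5)
  rep <- evaluate_knn(ds, cfg, seed = 1)
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$specificity, 1.0)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$auc, 1.0)
  # accounting identity: pooled counts = repeats x held-out size
  expect_equal(rep$n_test_total, 5 * (30 - 16))
  expect_error(evaluate_knn(make_ds(X[1:10, ], rep(0:1, 5)),
                            pipeline_config(n_train_per_class = 8)),
               "at least")
})

test_that("evaluation under permuted labels hovers at chance", {
  set.seed(19)
  X <- matrix(rnorm(46 * 8), 46, 8)
  y <- sample(rep(c(0L, 1L), 23))
  rep <- evaluate_knn(make_ds(X, y), pipeline_config(), seed = 2)
  expect_gt(rep$accuracy, 0.35); expect_lt(rep$accuracy, 0.65)
  expect_gt(rep$auc, 0.35); expect_lt(rep$auc, 0.65)
})

test_that("evaluation is reproducible bit-for-bit under a fixed seed", {
  set.seed(23)
  X <- matrix(rnorm(30 * 8), 30, 8)
  ds <- make_ds(X, rep(c(0L, 1L), each = 15))
  cfg <- pipeline_config(n_train_per_class = 10, n_repeats = 6)
  expect_identical(evaluate_knn(ds, cfg, seed = 7),
                   evaluate_knn(ds, cfg, seed = 7))
  expect_false(identical(evaluate_knn(ds, cfg, seed = 7)$confusion,
                         evaluate_knn(ds, cfg, seed = 8)$confusion))
})

test_that("the Welch t-test matches a hand computation and flags separation", {
  ident <- feature_ttest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$t_statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_false(ident$significant_05)

  nt <- c(0.12, 0.15, 0.19); tt <- c(0.40, 0.52, 0.44, 0.47)
  got <- feature_ttest(nt, tt)
  # Welch formula computed from scratch
  se <- sqrt(var(nt) / 3 + var(tt) / 4)
  t_hand <- (mean(tt) - mean(nt)) / se
  df_hand <- se^4 / ((var(nt) / 3)^2 / 2 + (var(tt) / 4)^2 / 3)
  expect_equal(got$t_statistic, t_hand, tolerance = 1e-6)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-6)
  expect_true(got$significant_05)

  set.seed(24)
  wide_nt <- rnorm(100, 0.16, 0.03)
  wide_t <- rnorm(100, 0.46, 0.14)
  expect_true(feature_ttest(wide_nt, wide_t)$significant_05)
  expect_error(feature_ttest(c(1), c(1, 2)), "at least 2")
  expect_error(feature_ttest(c(2, 2, 2), c(2, 2, 2)), "undefined t")
})

test_that("labeled datasets validate their inputs", {
  expect_error(labeled_dataset(matrix(1, 3, 8), c(0L, 1L)), "different")
  expect_error(labeled_dataset(matrix(1, 2, 8), c(0L, 2L)), "0 \\(NT\\)")
  expect_error(labeled_dataset(matrix(NA_real_, 2, 8), c(0L, 1L)),
               "non-finite")
})
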