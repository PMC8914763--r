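#' Assemble a labeled dataset of feature vectors
#'
#' @param features numeric matrix, one row per patient, columns in
#'   [feature_names] order (or a list of `"feature_vector"` objects).
#' @param labels integer vector of class labels, 0 = non-tumor (NT),
#'   1 = tumor (T).
#' @return An object of class `"labeled_dataset"` with `features`,
#'   `labels` and `feature_order`.
#' @export
labeled_dataset <- function(features, labels) {
  if (is.list(features) && !is.matrix(features))
    features <- do.call(rbind, lapply(features, as.numeric))
  features <- as.matrix(features)
  if (is.null(colnames(features)) && ncol(features) == length(feature_names))
    colnames(features) <- feature_names
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("features and labels have different lengths")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 (NT) or 1 (T)")
  if (any(!is.finite(features))) stop("non-finite feature values")
  structure(list(features = features, labels = labels,
                 feature_order = colnames(features)),
            class = "labeled_dataset")
}

# Training-set standardization statistics; zero-variance features are
# centered but not scaled.
train_scaling <- function(train_features) {
  mu <- colMeans(train_features)
  sd <- apply(train_features, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_scaling <- function(x, scaling) {
  sweep(sweep(x, 2L, scaling$mu, "-"), 2L, scaling$sd, "/")
}

#' Nearest-neighbor classification of one feature vector
#'
#' Assigns the class of the single nearest training vector under the
#' Euclidean distance over the eight features (k = 1). When
#' `config$standardize_features` is on, both the training matrix and the
#' test vector are z-scored with training-set statistics first, so that
#' no single feature dominates the distance. Distance ties are broken
#' toward the lowest training-row index. The returned `score` is the
#' signed nearest-neighbor margin, `d(nearest NT) - d(nearest T)`:
#' positive values lean toward the tumor class, and thresholding the
#' score at 0 reproduces the 1-NN label. The score provides the
#' threshold sweep for ROC analysis.
#'
#' @param test_vec numeric vector of the eight features.
#' @param train a [labeled_dataset()] containing both classes.
#' @param config a [pipeline_config()].
#' @return A list with `label` (0/1), `score` (signed margin) and
#'   `distance` (distance to the nearest neighbor).
#' @export
knn_classify <- function(test_vec, train, config = pipeline_config()) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (!all(c(0L, 1L) %in% train$labels))
    stop("training set must contain both classes")
  if (config$k_neighbors != 1L)
    stop("only k = 1 is supported")
  x <- train$features
  tv <- matrix(as.numeric(test_vec), 1L, ncol(x))
  if (config$standardize_features) {
    sc <- train_scaling(x)
    x <- apply_scaling(x, sc)
    tv <- apply_scaling(tv, sc)
  }
  d <- sqrt(rowSums(sweep(x, 2L, tv, "-")^2))
  nn <- which.min(d)  # first minimum = lowest training-row index
  list(label = train$labels[nn],
       score = min(d[train$labels == 0L]) - min(d[train$labels == 1L]),
       distance = d[nn])
}

#' Confusion-matrix metrics
#'
#' Sensitivity = TP / (TP + FN) (fraction of true tumor cases called
#' tumor); specificity = TN / (TN + FP); accuracy = (TP + TN) / total.
#'
#' @param cm a list or named vector with counts `tp`, `tn`, `fp`, `fn`
#'   (positive class = tumor).
#' @return Named numeric vector `(sensitivity, specificity, accuracy)`.
#' @export
confusion_metrics <- function(cm) {
  tp <- cm[["tp"]]; tn <- cm[["tn"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  if (tp + fn == 0) stop("undefined metric: sensitivity (no true T cases)")
  if (tn + fp == 0) stop("undefined metric: specificity (no true NT cases)")
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + tn + fp + fn))
}

#' ROC curve and AUC from classifier scores
#'
#' Sweeps every distinct score threshold (predict tumor when
#' `score >= threshold`) and reports the resulting false-positive /
#' true-positive rate pairs from (0, 0) to (1, 1). The AUC is computed
#' by the trapezoidal rule, which equals the tie-corrected
#' Mann-Whitney concordance statistic.
#'
#' @param scores numeric vector, larger = more tumor-leaning.
#' @param labels 0/1 vector, 1 = tumor (positive class).
#' @return A list with `roc_points` (data frame `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present for ROC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- cumsum(rle(s)$lengths)       # index of last tied score per block
  tpr <- c(0, cumsum(l == 1L)[last] / np)
  fpr <- c(0, cumsum(l == 0L)[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Repeated-split evaluation of the 1-NN classifier
#'
#' The evaluation protocol: in each of `n_repeats` repetitions, draw a
#' random training split of `n_train_per_class` members per class and
#' classify the remaining members; standardization statistics come from
#' the training portion only. The confusion counts and the signed
#' nearest-neighbor scores of all repetitions are pooled into a single
#' confusion matrix, metric set and ROC curve (pooling keeps the counts
#' integral; a single-summary report is what the protocol produces).
#'
#' @param dataset a [labeled_dataset()] with at least
#'   `n_train_per_class + 1` members per class.
#' @param config a [pipeline_config()].
#' @param seed integer seed; the whole evaluation is reproducible
#'   bit-for-bit given the seed.
#' @return An object of class `"classification_report"`: `confusion`
#'   (tp/tn/fp/fn), `sensitivity`, `specificity`, `accuracy`,
#'   `roc_points`, `auc`, `n_repeats`, `n_test_total`, plus the pooled
#'   `scores` and `truth` vectors.
#' @export
evaluate_knn <- function(dataset, config = pipeline_config(),
                         seed = config$rng_seed) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  idx0 <- which(dataset$labels == 0L); idx1 <- which(dataset$labels == 1L)
  ntr <- config$n_train_per_class
  if (length(idx0) < ntr + 1L || length(idx1) < ntr + 1L)
    stop(sprintf("need at least %d members per class (have %d NT, %d T)",
                 ntr + 1L, length(idx0), length(idx1)))
  cm <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  scores <- numeric(0); truth <- integer(0)
  with_seed(seed, {
    for (rep in seq_len(config$n_repeats)) {
      tr <- c(sample(idx0, ntr), sample(idx1, ntr))
      te <- setdiff(seq_along(dataset$labels), tr)
      train <- labeled_dataset(dataset$features[tr, , drop = FALSE],
                               dataset$labels[tr])
      for (i in te) {
        res <- knn_classify(dataset$features[i, ], train, config)
        y <- dataset$labels[i]
        key <- if (y == 1L && res$label == 1L) "tp"
          else if (y == 0L && res$label == 0L) "tn"
          else if (y == 0L) "fp" else "fn"
        cm[key] <- cm[key] + 1L
        scores <- c(scores, res$score); truth <- c(truth, y)
      }
    }
  })
  met <- confusion_metrics(cm)
  roc <- roc_curve(scores, truth)
  structure(list(confusion = as.list(cm),
                 sensitivity = met[["sensitivity"]],
                 specificity = met[["specificity"]],
                 accuracy = met[["accuracy"]],
                 roc_points = roc$roc_points, auc = roc$auc,
                 n_repeats = config$n_repeats,
                 n_test_total = sum(cm), scores = scores, truth = truth),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cm <- x$confusion
  cat("<classification_report>\n")
  cat(sprintf("  pooled over %d repeats, %d test decisions\n",
              x$n_repeats, x$n_test_total))
  cat(sprintf("  confusion: TP %d  FN %d  FP %d  TN %d\n",
              cm$tp, cm$fn, cm$fp, cm$tn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  AUC %.4f\n", x$auc))
  invisible(x)
}

#' Write a classification report as key-value text
#'
#' @param report a `"classification_report"`.
#' @param path output file; ROC points go to `<path>` with suffix
#'   `_roc.tsv` alongside.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  cm <- report$confusion
  lines <- c(sprintf("n_repeats: %d", report$n_repeats),
             sprintf("n_test_total: %d", report$n_test_total),
             sprintf("tp: %d", cm$tp), sprintf("tn: %d", cm$tn),
             sprintf("fp: %d", cm$fp), sprintf("fn: %d", cm$fn),
             sprintf("sensitivity: %.10g", report$sensitivity),
             sprintf("specificity: %.10g", report$specificity),
             sprintf("accuracy: %.10g", report$accuracy),
             sprintf("auc: %.10g", report$auc))
  writeLines(lines, path)
  roc_path <- sub("(\\.[A-Za-z0-9]+)?$", "_roc.tsv", path)
  utils::write.table(round(report$roc_points, 10), roc_path[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-feature two-group Welch t-test
#'
#' Tests whether a feature's values differ between the non-tumor and
#' tumor groups, using the unequal-variance (Welch) two-sample t-test:
#' the group spreads of asymmetry features differ by up to an order of
#' magnitude, which rules out the pooled-variance form.
#'
#' @param nt_values,t_values numeric vectors, at least 2 values each.
#' @return A list with `t_statistic`, `p_value` (two-sided) and
#'   `significant_05`.
#' @export
feature_ttest <- function(nt_values, t_values) {
  if (length(nt_values) < 2L || length(t_values) < 2L)
    stop("need at least 2 values per group")
  res <- tryCatch(
    stats::t.test(t_values, nt_values, var.equal = FALSE),
    error = function(e)
      stop("undefined t statistic: ", conditionMessage(e), call. = FALSE))
  list(t_statistic = unname(res$statistic), p_value = res$p.value,
       significant_05 = res$p.value < 0.05)
}
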