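#' @title Metrics and cross-validation
#' @description Confusion counts, sensitivity/specificity/accuracy, rank-based
#'   AUC, and a stratified k-fold cross-validation harness for the binary
#'   stage classifiers.
#' @name evaluation
NULL

#' Confusion counts of binary predictions against truths
#'
#' @param predictions Binary (0/1 or logical) predicted labels.
#' @param truths Binary true labels, same length.
#' @return A list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predictions, truths) {
  predictions <- as.integer(as.logical(predictions))
  truths <- as.integer(as.logical(truths))
  if (length(predictions) != length(truths)) {
    stop("predictions and truths differ in length")
  }
  structure(list(
    TP = sum(predictions == 1 & truths == 1),
    FP = sum(predictions == 1 & truths == 0),
    TN = sum(predictions == 0 & truths == 0),
    FN = sum(predictions == 0 & truths == 1)
  ), class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`. A zero denominator yields `NA`
#' (undefined), never a silent 0.
#'
#' @param c A [confusion()] result.
#' @return A value in `[0, 1]`, or `NA_real_` when undefined.
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) return(NA_real_)
  c$TP / (c$TP + c$FN)
}

#' @rdname sensitivity
#' @export
specificity <- function(c) {
  if (c$TN + c$FP == 0) return(NA_real_)
  c$TN / (c$TN + c$FP)
}

#' @rdname sensitivity
#' @export
accuracy <- function(c) {
  n <- c$TP + c$FP + c$TN + c$FN
  if (n == 0) return(NA_real_)
  (c$TP + c$TN) / n
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs in
#' which the positive scores higher, with ties counted one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truths Binary true labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, truths) {
  truths <- as.logical(truths)
  if (length(scores) != length(truths)) stop("scores and truths differ in length")
  n_pos <- sum(truths); n_neg <- sum(!truths)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)   # average ranks handle ties as 1/2
  (sum(r[truths]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified k-fold cross-validation
#'
#' Positive and negative samples are each shuffled (seeded) and dealt
#' round-robin into `k` folds, so every fold contains both classes whenever
#' counts permit and fold sizes differ by at most one per class. For each
#' fold, `trainer` is fitted on the remaining data and scored on the held-out
#' fold.
#'
#' @param x List of feature objects.
#' @param y Binary labels (0/1 or logical).
#' @param trainer `function(x_train, y_train)` returning a scoring function
#'   `function(x_list) -> numeric eta vector`.
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment.
#' @param threshold Score threshold for the positive call (default 0.5).
#' @return A list with `folds` (data frame of per-fold `sensitivity`,
#'   `specificity`, `accuracy`, `auc`) and `mean` (named means, `NA`s
#'   removed), plus the fold assignment.
#' @export
kfold_cv <- function(x, y, trainer, k = 10L, seed = 1L, threshold = 0.5) {
  y <- as.integer(as.logical(y))
  n <- length(y)
  stopifnot(length(x) == n)
  if (n < k) stop("dataset size ", n, " is smaller than k = ", k)
  fold <- integer(n)
  with_seed(derive_seed(seed, "cv-folds"), {
    # deal each class round-robin, continuing the rotation across classes so
    # overall fold sizes differ by at most one even when a class has < k
    # members (e.g. leave-one-out)
    order_all <- c(sample(which(y == 1L)), sample(which(y == 0L)))
    fold[order_all] <- rep_len(seq_len(k), n)
  })
  rows <- lapply(seq_len(k), function(f) {
    test <- which(fold == f)
    train <- which(fold != f)
    predictor <- trainer(x[train], y[train])
    eta <- predictor(x[test])
    cc <- confusion(eta >= threshold, y[test])
    fold_auc <- if (length(unique(y[test])) == 2L) auc(eta, y[test]) else NA_real_
    data.frame(fold = f, n = length(test),
               sensitivity = sensitivity(cc), specificity = specificity(cc),
               accuracy = accuracy(cc), auc = fold_auc)
  })
  folds <- do.call(rbind, rows)
  metric_cols <- c("sensitivity", "specificity", "accuracy", "auc")
  list(folds = folds,
       mean = colMeans(folds[metric_cols], na.rm = TRUE),
       assignment = fold)
}

#' Per-stage OvR metric table for a trained bundle
#'
#' Evaluates each stage's binary classifier on a labelled record set and
#' reports one row per stage (sensitivity, specificity, accuracy, AUC) --
#' the standard per-stage reporting shape for this pipeline.
#'
#' @param bundle A [train_staging_bundle()] result.
#' @param records List of labelled `patient_record`s.
#' @param threshold Positive-call threshold on `eta`.
#' @return A data frame with columns `stage`, `sensitivity`, `specificity`,
#'   `accuracy`, `auc`.
#' @export
stage_metrics <- function(bundle, records, threshold = 0.5) {
  stopifnot(inherits(bundle, "stage_model_bundle"))
  xs <- lapply(records, function(r)
    embed_document(render_text(r, bundle$ranges), bundle$embedding,
                   bundle$max_len))
  rows <- lapply(stage_levels, function(li) {
    truth <- vapply(records, function(r) li %in% r$stages, logical(1))
    eta <- cnn_predict(bundle$models[[li]], xs)
    cc <- confusion(eta >= threshold, truth)
    stage_auc <- if (length(unique(truth)) == 2L) auc(eta, truth) else NA_real_
    data.frame(stage = li, sensitivity = sensitivity(cc),
               specificity = specificity(cc), accuracy = accuracy(cc),
               auc = stage_auc)
  })
  do.call(rbind, rows)
}
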