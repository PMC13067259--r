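# Confusion matrices, classification metrics, stratified k-fold
# cross-validation and the with/without-FSSA comparison harness.

#' Confusion matrix
#'
#' `counts[t, p]` is the number of samples with true class `t` predicted as
#' class `p` (0-based labels `0..C-1`).
#'
#' @param y_true True labels in `0..C-1`.
#' @param y_pred Predicted labels, same length.
#' @param C Number of classes.
#' @return `C x C` integer matrix with dimnames set to the class indices.
#' @export
confusion_matrix <- function(y_true, y_pred, C) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  C <- as.integer(C)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) > 0 &&
      (min(y_true, y_pred) < 0L || max(y_true, y_pred) > C - 1L))
    stop("labels must lie in [0, C - 1]")
  cm <- matrix(0L, C, C, dimnames = list(true = 0:(C - 1L),
                                         predicted = 0:(C - 1L)))
  for (k in seq_along(y_true))
    cm[y_true[k] + 1L, y_pred[k] + 1L] <- cm[y_true[k] + 1L, y_pred[k] + 1L] + 1L
  cm
}

#' Metrics from binary confusion counts
#'
#' accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, sensitivity (recall)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`. Any `0/0` yields 0 by
#' convention.
#'
#' @param TP,TN,FP,FN Non-negative counts.
#' @return Named list with the four metrics.
#' @export
binary_metrics <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  list(accuracy    = safe_div(TP + TN, TP + TN + FP + FN),
       precision   = safe_div(TP, TP + FP),
       sensitivity = safe_div(TP, TP + FN),
       specificity = safe_div(TN, TN + FP))
}

#' Summary metrics of a multiclass confusion matrix
#'
#' For each class `c`, the one-vs-rest counts are `TP = counts[c, c]`,
#' `FN = row c minus TP`, `FP = column c minus TP`, `TN = the rest`, and
#' [binary_metrics()] gives the per-class values. The single-number
#' summary follows the usual reporting convention for multiclass tasks:
#' `accuracy` is the overall fraction of correct predictions
#' (`sum(diag) / total`, so chance on balanced `C`-class data is `1/C`),
#' while `precision`, `sensitivity` and `specificity` are macro-averaged
#' (unweighted mean over the per-class one-vs-rest values).
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return List with `per_class` (data.frame of per-class one-vs-rest
#'   metrics) and `macro` (named list of the four summary metrics).
#' @export
macro_metrics <- function(cm) {
  C <- nrow(cm)
  if (C < 2L) stop("need at least 2 classes")
  total <- sum(cm)
  rows <- lapply(seq_len(C), function(c) {
    TP <- cm[c, c]
    FN <- sum(cm[c, ]) - TP
    FP <- sum(cm[, c]) - TP
    TN <- total - TP - FN - FP
    as.data.frame(binary_metrics(TP, TN, FP, FN))
  })
  per_class <- do.call(rbind, rows)
  per_class$class <- rownames(cm)
  macro <- as.list(colMeans(per_class[, c("precision",
                                          "sensitivity", "specificity")]))
  macro$accuracy <- if (total > 0) sum(diag(cm)) / total else 0
  macro <- macro[c("accuracy", "precision", "sensitivity", "specificity")]
  list(per_class = per_class, macro = macro)
}

#' Stratified k-fold partition
#'
#' Splits sample indices into `k` disjoint validation folds. In stratified
#' mode (default) each class is divided as evenly as possible across folds,
#' so fold class proportions match the data within one sample.
#'
#' @param labels Class label vector (its length defines `n`).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param stratified Preserve class proportions per fold.
#' @return List of `k` integer index vectors: a partition of `1..n`.
#' @export
kfold_split <- function(labels, k, seed = 1L, stratified = TRUE) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2")
  n <- length(labels)
  folds <- vector("list", k)
  with_seed(seed, {
    if (stratified) {
      if (any(table(labels) < k))
        stop("every class needs at least k members for stratified folds")
      for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        fold_of <- rep_len(seq_len(k), length(idx))
        for (f in seq_len(k))
          folds[[f]] <- c(folds[[f]], idx[fold_of == f])
      }
    } else {
      if (n < k) stop("need at least k samples")
      idx <- sample(n)
      fold_of <- rep_len(seq_len(k), n)
      for (f in seq_len(k)) folds[[f]] <- idx[fold_of == f]
    }
  })
  lapply(folds, sort)
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold, fits on the k-1 training folds only (by default
#' [fit_qdnn()], i.e. FSSA refit inside the training fold followed by
#' one-vs-rest training) and evaluates on the held-out fold. No validation
#' information reaches the fit: `fit_fn` sees only training-fold rows.
#'
#' @param F A [feature_matrix()].
#' @param k Number of folds.
#' @param seed Seed controlling fold membership and per-fold fits.
#' @param fit_fn `function(train_fm, fold_seed) -> model`.
#' @param predict_fn `function(model, fm) -> predicted label vector`.
#' @param stratified Stratified folds (default).
#' @return List with `folds` (per-fold list of `metrics` and `confusion`),
#'   `mean` (arithmetic mean of the per-fold macro metrics), and
#'   `confusion` (pooled confusion matrix over all folds).
#' @export
run_cv <- function(F, k = 5L, seed = 1L,
                   fit_fn = function(train_fm, fold_seed)
                     fit_qdnn(train_fm, qdnn_architecture(4L, 2L),
                              train_config(seed = fold_seed)),
                   predict_fn = function(model, fm)
                     predict(model, fm)$labels,
                   stratified = TRUE) {
  stopifnot(inherits(F, "feature_matrix"))
  classes <- sort(unique(F$labels))
  C <- length(classes)
  folds <- kfold_split(F$labels, k, seed = seed, stratified = stratified)
  pooled <- matrix(0L, C, C, dimnames = list(true = 0:(C - 1L),
                                             predicted = 0:(C - 1L)))
  fold_out <- vector("list", k)
  for (f in seq_len(k)) {
    val_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(F$labels), val_idx)
    train_fm <- feature_matrix(F$values[train_idx, , drop = FALSE],
                               F$labels[train_idx], F$feature_names)
    val_fm <- feature_matrix(F$values[val_idx, , drop = FALSE],
                             F$labels[val_idx], F$feature_names)
    model <- fit_fn(train_fm, seed + 17L * f)
    pred <- predict_fn(model, val_fm)
    cm <- confusion_matrix(match(val_fm$labels, classes) - 1L,
                           match(pred, classes) - 1L, C)
    pooled <- pooled + cm
    fold_out[[f]] <- list(fold = f, confusion = cm,
                          metrics = macro_metrics(cm)$macro)
  }
  metric_names <- c("accuracy", "precision", "sensitivity", "specificity")
  mean_metrics <- lapply(metric_names, function(m)
    mean(vapply(fold_out, function(x) x$metrics[[m]], numeric(1))))
  names(mean_metrics) <- metric_names
  list(folds = fold_out, mean = mean_metrics, confusion = pooled)
}
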