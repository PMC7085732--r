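# Split, metrics, and model evaluation. FALL is the positive class
# throughout: sensitivity is fall recall, specificity is the false-alarm
# complement.

#' Stratified 60/20/20 train/validation/test split
#'
#' Randomly partitions a labeled collection while preserving the class
#' proportions: within each class the 60/20/20 targets are met by
#' largest-remainder allocation, so every subset's class count is within one
#' trace of the exact proportional share. Deterministic given `seed`.
#'
#' @param x list of [inertial_trace] objects, or a factor/character vector
#'   of ADL/FALL labels.
#' @param seed integer seed.
#' @param ratios train/validation/test proportions (must sum to 1).
#' @return object of class `split_assignment`: list with integer index
#'   vectors `train`, `val`, `test` (disjoint, jointly covering the input),
#'   plus `ratios` and `seed`.
#' @export
split_dataset <- function(x, seed, ratios = c(0.6, 0.2, 0.2)) {
  labels <- if (is.list(x)) trace_labels(x)
            else factor(as.character(x), levels = c("ADL", "FALL"))
  if (anyNA(labels))
    stop_fallcnn("labels must be ADL or FALL", "fallcnn_config_error")
  if (abs(sum(ratios) - 1) > 1e-9 || length(ratios) != 3L || any(ratios <= 0))
    stop_fallcnn("`ratios` must be three positive proportions summing to 1",
                 "fallcnn_config_error")
  counts <- table(labels)
  if (any(counts < 5L))
    stop_fallcnn(sprintf(
      "each class needs >= 5 traces to populate three subsets (ADL %d, FALL %d)",
      counts["ADL"], counts["FALL"]), "fallcnn_split_error")
  alloc <- function(n) {
    raw <- n * ratios
    base <- floor(raw)
    k <- n - sum(base)
    if (k > 0) {
      ord <- order(raw - base, decreasing = TRUE)  # ties favour train first
      base[ord[seq_len(k)]] <- base[ord[seq_len(k)]] + 1
    }
    as.integer(base)
  }
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      a <- alloc(length(idx))
      parts$train <- c(parts$train, idx[seq_len(a[1])])
      parts$val <- c(parts$val, idx[a[1] + seq_len(a[2])])
      parts$test <- c(parts$test, idx[a[1] + a[2] + seq_len(a[3])])
    }
  })
  structure(list(train = sort(parts$train), val = sort(parts$val),
                 test = sort(parts$test), ratios = ratios,
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> train %d / val %d / test %d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Confusion counts of predictions against truth (FALL positive)
#'
#' @param predicted,truth factors or character vectors of ADL/FALL labels.
#' @return object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN` (summing to the number of windows).
#' @export
confusion_counts <- function(predicted, truth) {
  predicted <- factor(as.character(predicted), levels = c("ADL", "FALL"))
  truth <- factor(as.character(truth), levels = c("ADL", "FALL"))
  if (length(predicted) != length(truth) || anyNA(predicted) || anyNA(truth))
    stop_fallcnn("predictions and truth must be equal-length ADL/FALL vectors",
                 "fallcnn_config_error")
  structure(list(TP = sum(predicted == "FALL" & truth == "FALL"),
                 TN = sum(predicted == "ADL" & truth == "ADL"),
                 FP = sum(predicted == "FALL" & truth == "ADL"),
                 FN = sum(predicted == "ADL" & truth == "FALL")),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Computes the three binary quality metrics as percentages:
#' `Se = 100 * TP / (FN + TP)` (fall recall),
#' `Sp = 100 * TN / (FP + TN)` (false-alarm avoidance),
#' `Acc = 100 * (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts a [confusion_counts()] object, or a named list/vector with
#'   `TP`, `TN`, `FP`, `FN`.
#' @return object of class `metrics_report`: list with `sensitivity`,
#'   `specificity`, `accuracy` in `[0, 100]`.
#' @examples
#' compute_metrics(list(TP = 45, FN = 5, TN = 90, FP = 10))  # 90 / 90 / 90
#' @export
compute_metrics <- function(counts) {
  cts <- lapply(c("TP", "TN", "FP", "FN"), function(k) {
    v <- counts[[k]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v != round(v))
      stop_fallcnn(sprintf("`%s` must be a non-negative integer count", k),
                   "fallcnn_config_error")
    as.numeric(v)
  })
  names(cts) <- c("TP", "TN", "FP", "FN")
  if (cts$TP + cts$FN == 0)
    stop_fallcnn("no FALL windows evaluated: sensitivity denominator FN + TP is zero",
                 "fallcnn_metrics_error")
  if (cts$TN + cts$FP == 0)
    stop_fallcnn("no ADL windows evaluated: specificity denominator FP + TN is zero",
                 "fallcnn_metrics_error")
  structure(list(sensitivity = 100 * cts$TP / (cts$FN + cts$TP),
                 specificity = 100 * cts$TN / (cts$FP + cts$TN),
                 accuracy = 100 * (cts$TP + cts$TN) /
                   (cts$TP + cts$TN + cts$FP + cts$FN)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> Se %.2f%% / Sp %.2f%% / Acc %.2f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Evaluate a trained model on labeled test windows
#'
#' @param model a trained `fallcnn_model`.
#' @param x test window matrix (or [windows_from_traces()] list).
#' @param labels test labels (ignored if `x` carries its own `labels`).
#' @return list with `counts` ([confusion_counts()]) and `metrics`
#'   ([compute_metrics()]).
#' @export
evaluate_model <- function(model, x, labels = NULL) {
  if (is.list(x) && !is.null(x$x)) {
    labels <- labels %||% x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  if (nrow(x) == 0L)
    stop_fallcnn("test set is empty", "fallcnn_config_error")
  if (is.null(labels) || length(labels) != nrow(x))
    stop_fallcnn("labels must accompany every test window", "fallcnn_config_error")
  pred <- predict(model, x)
  counts <- confusion_counts(pred$labels, labels)
  list(counts = counts, metrics = compute_metrics(counts))
}
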