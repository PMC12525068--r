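# Evaluation suite: confusion matrix, per-class and macro
# precision/recall/F1, accuracy, Matthews correlation coefficient, one-vs-rest
# ROC/AUC, and stratified cross-validation with mean +/- sd aggregation.
#
# Note on the precision/recall definitions: the standard one-vs-rest forms
# are used — precision = TP/(TP+FP) (column-wise), recall = TP/(TP+FN)
# (row-wise). Some published write-ups of these formulas swap the two
# denominators in print; the standard definitions are what per-class tables
# labeled "precision"/"recall" actually report, and they are what this module
# computes.

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes:
#' `counts[i, j]` = number of samples with true class `i` predicted as `j`.
#'
#' @param y_true,y_pred Integer labels in `1..n_classes`, or factors sharing
#'   levels.
#' @param n_classes Number of classes; defaults to the number of factor
#'   levels or the maximum observed label.
#' @param class_names Optional class labels for the dimnames.
#' @return An `n_classes x n_classes` integer matrix of class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = NULL,
                             class_names = NULL) {
  if (is.factor(y_true) && is.null(class_names)) class_names <- levels(y_true)
  if (is.factor(y_true)) y_true <- as.integer(y_true)
  if (is.factor(y_pred)) y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (is.null(n_classes)) {
    n_classes <- max(length(class_names), y_true, y_pred)
  }
  n_classes <- as.integer(n_classes)
  if (any(y_true < 1L | y_true > n_classes) || any(y_pred < 1L | y_pred > n_classes)) {
    stop(sprintf("labels outside 1..%d", n_classes), call. = FALSE)
  }
  if (is.null(class_names)) class_names <- as.character(seq_len(n_classes))
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = class_names, predicted = class_names))
  for (k in seq_along(y_true)) {
    cm[y_true[k], y_pred[k]] <- cm[y_true[k], y_pred[k]] + 1L
  }
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Per-class precision, recall and F1 (one-vs-rest)
#'
#' For class c: TP is the diagonal entry, FP the rest of its column, FN the
#' rest of its row. Zero denominators yield 0 with a warning (e.g. a class
#' that is never predicted has precision 0 by convention).
#'
#' @param cm A `confusion_matrix` (or plain square count matrix).
#' @return Data frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
per_class_prf <- function(cm) {
  cm <- unclass(cm)
  k <- nrow(cm)
  nm <- rownames(cm)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what, cls) {
    out <- numeric(length(num))
    bad <- den == 0
    if (any(bad)) {
      warning(sprintf("%s undefined for class(es) %s (zero denominator); reported as 0",
                      what, paste(cls[bad], collapse = ", ")), call. = FALSE)
    }
    out[!bad] <- num[!bad] / den[!bad]
    out
  }
  precision <- safe_div(tp, tp + fp, "precision", nm)
  recall <- safe_div(tp, tp + fn, "recall", nm)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(class = nm, precision = precision, recall = recall, f1 = f1,
             support = as.integer(rowSums(cm)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Matthews correlation coefficient
#'
#' For a 2x2 matrix this is the familiar binary form
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' and for more classes the standard multiclass generalization over the full
#' confusion matrix
#' \deqn{MCC = \frac{c \cdot s - \sum_k t_k p_k}
#'   {\sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}}}
#' (c = trace, s = total, t/p = row/column sums), which reduces exactly to
#' the binary form when there are two classes. A zero denominator (e.g. all
#' predictions in one class) yields 0 by convention.
#'
#' @param cm A confusion matrix.
#' @return A number in \[-1, 1\].
#' @export
mcc <- function(cm) {
  cm <- unclass(cm)
  s <- sum(cm)
  c_tr <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c_tr * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' One-vs-rest ROC AUC per class
#'
#' AUC for class c uses column c of the probability matrix as the score and
#' membership of class c as the positive label, computed from the
#' Mann-Whitney rank statistic with midranks for ties (equivalent to the
#' trapezoidal area under the ROC curve).
#'
#' @param y_true Integer labels in `1..n_classes` or a factor.
#' @param probabilities n x n_classes matrix with rows summing to 1.
#' @param n_classes Number of classes (defaults to `ncol(probabilities)`).
#' @return Named numeric vector of per-class AUCs; `NA` for classes absent
#'   from `y_true` (AUC undefined).
#' @export
roc_auc_ovr <- function(y_true, probabilities, n_classes = ncol(probabilities)) {
  nm <- colnames(probabilities)
  if (is.factor(y_true)) {
    if (is.null(nm)) nm <- levels(y_true)
    y_true <- as.integer(y_true)
  }
  if (is.null(nm)) nm <- as.character(seq_len(n_classes))
  if (nrow(probabilities) != length(y_true)) {
    stop("`probabilities` must have one row per label", call. = FALSE)
  }
  rs <- rowSums(probabilities)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  auc <- stats::setNames(rep(NA_real_, n_classes), nm)
  for (c in seq_len(n_classes)) {
    pos <- y_true == c
    n_pos <- sum(pos); n_neg <- sum(!pos)
    if (n_pos == 0L || n_neg == 0L) next
    r <- rank(probabilities[, c], ties.method = "average")
    auc[c] <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  auc
}

#' Full metric report
#'
#' Bundles the confusion matrix with per-class and macro-averaged
#' precision/recall/F1, accuracy, multiclass MCC, and (when probabilities are
#' supplied) per-class one-vs-rest AUC. Macro averages are unweighted means
#' of the per-class values. All values are stored on the 0-1 scale; the
#' print method can render 0-100.
#'
#' @param y_true,y_pred Labels as in [confusion_matrix()].
#' @param probabilities Optional probability matrix for ROC/AUC.
#' @param n_classes,class_names Passed to [confusion_matrix()].
#' @return An object of class `metric_report`.
#' @export
metric_report <- function(y_true, y_pred, probabilities = NULL,
                          n_classes = NULL, class_names = NULL) {
  cm <- confusion_matrix(y_true, y_pred, n_classes, class_names)
  prf <- per_class_prf(cm)
  rep <- list(
    confusion = cm,
    per_class = prf,
    macro_precision = mean(prf$precision),
    macro_recall = mean(prf$recall),
    macro_f1 = mean(prf$f1),
    accuracy = sum(diag(unclass(cm))) / sum(cm),
    mcc = mcc(cm)
  )
  if (!is.null(probabilities)) {
    rep$auc <- roc_auc_ovr(y_true, probabilities, n_classes = nrow(cm))
  }
  class(rep) <- "metric_report"
  rep
}

#' @param x A `metric_report`.
#' @param scale `1` (default, 0-1 values) or `100` (percent rendering).
#' @param ... Unused.
#' @rdname metric_report
#' @export
print.metric_report <- function(x, scale = 1, ...) {
  f <- function(v) formatC(v * scale, digits = if (scale == 100) 2 else 4,
                           format = "f", width = 9)
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x$confusion))
  cat("\n          precision    recall        f1  support\n")
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("%-9s %s %s %s %8d\n", x$per_class$class[i],
                f(x$per_class$precision[i]), f(x$per_class$recall[i]),
                f(x$per_class$f1[i]), x$per_class$support[i]))
  }
  cat(sprintf("%-9s %s %s %s\n", "macro", f(x$macro_precision),
              f(x$macro_recall), f(x$macro_f1)))
  cat(sprintf("\naccuracy: %s   MCC: %s\n", f(x$accuracy), f(x$mcc)))
  if (!is.null(x$auc)) {
    cat("per-class AUC:", paste(sprintf("%s %.4f", names(x$auc), x$auc),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a metric report as CSV
#'
#' One row per class plus a macro row; columns precision, recall, f1,
#' support (accuracy and MCC are repeated on the macro row).
#'
#' @param report A `metric_report`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  pc <- report$per_class
  macro <- data.frame(class = "macro", precision = report$macro_precision,
                      recall = report$macro_recall, f1 = report$macro_f1,
                      support = sum(pc$support), stringsAsFactors = FALSE)
  out <- rbind(pc, macro)
  out$accuracy <- c(rep(NA, nrow(pc)), report$accuracy)
  out$mcc <- c(rep(NA, nrow(pc)), report$mcc)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Stratified k-fold cross-validation
#'
#' Partitions the dataset into k stratified folds (each sample appears in
#' exactly one validation fold; fold assignment is deterministic given
#' `seed`), calls a user-supplied train-and-predict procedure per fold, and
#' aggregates per-class precision/recall/F1 as mean and sample standard
#' deviation across folds.
#'
#' @param frames List of frames (or any sample list the procedure accepts).
#' @param labels Integer labels in `1..n_classes` or a factor.
#' @param k Number of folds (>= 2, default 5).
#' @param build_and_train `function(train_frames, train_labels, val_frames,
#'   val_labels, fold)` returning a list with `labels` (predicted) and
#'   optionally `probs`.
#' @param seed Integer seed for the fold assignment.
#' @param n_classes Number of classes (defaults to `max(labels)` / factor
#'   levels).
#' @return List with `fold_reports` (list of `metric_report`), `summary`
#'   (data frame: class, metric, mean, sd), and `fold_assignment`.
#' @export
cross_validate <- function(frames, labels, k = 5L, build_and_train,
                           seed = 1L, n_classes = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (length(frames) < k) stop("dataset smaller than k", call. = FALSE)
  class_names <- if (is.factor(labels)) levels(labels) else NULL
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  if (is.null(n_classes)) n_classes <- max(y, length(class_names))
  n <- length(y)
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (c in seq_len(n_classes)) {
      rows <- which(y == c)
      if (length(rows) == 0L) next
      if (length(rows) < k) {
        warning(sprintf("class %d has fewer samples (%d) than folds (%d); stratification relaxed",
                        c, length(rows), k), call. = FALSE)
      }
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    va <- which(fold == f)
    tr <- which(fold != f)
    pred <- build_and_train(frames[tr], y[tr], frames[va], y[va], f)
    fold_reports[[f]] <- metric_report(y[va], pred$labels,
                                       probabilities = pred$probs,
                                       n_classes = n_classes,
                                       class_names = class_names)
  }
  nm <- if (is.null(class_names)) as.character(seq_len(n_classes)) else class_names
  rows <- list()
  for (metric in c("precision", "recall", "f1")) {
    for (ci in seq_len(n_classes)) {
      vals <- vapply(fold_reports, function(r) r$per_class[[metric]][ci], numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        class = nm[ci], metric = metric,
        mean = mean(vals), sd = stats::sd(vals), stringsAsFactors = FALSE)
    }
  }
  for (metric in c("accuracy", "mcc")) {
    vals <- vapply(fold_reports, function(r) r[[metric]], numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      class = "(all)", metric = metric,
      mean = mean(vals), sd = stats::sd(vals), stringsAsFactors = FALSE)
  }
  list(fold_reports = fold_reports,
       summary = do.call(rbind, rows),
       fold_assignment = fold)
}
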