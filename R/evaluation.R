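#' Confusion matrix (rows = actual, columns = predicted)
#'
#' @param actual,predicted equal-length label vectors over \code{classes}.
#' @param classes ordered class set; defaults to the sorted union of observed
#'   labels.
#' @return object of class \code{confusion_matrix}: integer \code{counts}
#'   (K x K) plus \code{percent}, the row-normalized percentage view.
#' @export
confusion <- function(actual, predicted, classes = NULL) {
  if (length(actual) != length(predicted)) {
    abort_validation("actual and predicted must have equal length")
  }
  if (is.null(classes)) classes <- sort(unique(c(actual, predicted)))
  if (!all(actual %in% classes) || !all(predicted %in% classes)) {
    abort_validation("label outside the declared class set")
  }
  fa <- factor(actual, levels = classes)
  fp <- factor(predicted, levels = classes)
  counts <- table(actual = fa, predicted = fp)
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(actual = as.character(classes),
                                   predicted = as.character(classes)))
  rs <- rowSums(counts)
  percent <- 100 * counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, percent = percent, classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = actual, columns = predicted\n")
  print(x$counts)
  invisible(x)
}

#' Per-class and aggregate classification metrics
#'
#' One-vs-rest from the confusion matrix: recall = TP/(TP+FN),
#' precision = TP/(TP+FP), F1 = 2PR/(P+R); accuracy = trace/total;
#' macro average = unweighted mean over classes; weighted average =
#' support-weighted mean.  Classes with a zero denominator report 0 with a
#' warning.
#'
#' @param cm a \code{\link{confusion}} matrix.
#' @return object of class \code{class_metrics}: \code{per_class} data frame
#'   (precision, recall, f1, support), \code{accuracy}, \code{macro_avg} and
#'   \code{weighted_avg} (each a named vector over precision/recall/f1).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$counts
  total <- sum(m)
  if (total == 0) abort_validation("confusion matrix is empty")
  K <- nrow(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning(sprintf("%s undefined for class(es) %s; reporting 0", what,
                      paste(cm$classes[bad], collapse = ", ")), call. = FALSE)
    }
    out <- ifelse(bad, 0, num / ifelse(den == 0, 1, den))
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  support <- rowSums(m)
  w <- support / total
  per_class <- data.frame(class = as.character(cm$classes),
                          precision = precision, recall = recall, f1 = f1,
                          support = support, row.names = NULL)
  agg <- function(v, weights = NULL) {
    if (is.null(weights)) mean(v) else sum(v * weights)
  }
  structure(list(
    per_class = per_class,
    accuracy = sum(tp) / total,
    macro_avg = c(precision = agg(precision), recall = agg(recall), f1 = agg(f1)),
    weighted_avg = c(precision = agg(precision, w), recall = agg(recall, w),
                     f1 = agg(f1, w))
  ), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("<class_metrics>\n")
  print(x$per_class, digits = 3)
  cat(sprintf("accuracy %.4f\n", x$accuracy))
  cat("macro   :", paste(sprintf("%s %.3f", names(x$macro_avg), x$macro_avg), collapse = "  "), "\n")
  cat("weighted:", paste(sprintf("%s %.3f", names(x$weighted_avg), x$weighted_avg), collapse = "  "), "\n")
  invisible(x)
}

#' ROC curve and area for a binary cascade node
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' score >= threshold), yielding the TPR/FPR staircase; the area is computed
#' by the trapezoid rule.
#'
#' @param scores positive-branch probabilities.
#' @param truths logical or 0/1 vector of the positive class.
#' @return list with \code{points} (data.frame: threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
roc_curve <- function(scores, truths) {
  truths <- as.logical(truths)
  if (length(scores) != length(truths)) abort_validation("length mismatch")
  np <- sum(truths); nn <- sum(!truths)
  if (np == 0 || nn == 0) abort_validation("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & truths) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !truths) / nn, 0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}
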