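# Confusion-matrix metrics: per-class precision/recall/F-measure and
# overall accuracy, reported as percentages rounded to one decimal, with
# full-precision values kept internally.

#' Compute classification metrics from a confusion matrix
#'
#' Rows are actual classes, columns predicted, same order. Percentages:
#' `precision_c = 100 * M[c,c] / colsum(c)`, `recall_c = 100 * M[c,c] /
#' rowsum(c)`, F the harmonic mean of the two, `accuracy = 100 * trace /
#' total`. A zero column sum makes that precision undefined (`NaN`, with a
#' warning).
#'
#' @param confusion Square nonnegative integer matrix with at least one
#'   observation.
#' @return Object of class `evaluation_report`: the confusion matrix,
#'   per-class `precision`, `recall`, `f_measure` (percent, full
#'   precision), `accuracy`, and `support` (row sums). `print()` rounds to
#'   one decimal.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stopf("confusion matrix must be square")
  if (any(confusion < 0)) stopf("confusion matrix entries must be nonnegative")
  total <- sum(confusion)
  if (total < 1) stopf("confusion matrix must hold at least one observation")
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- paste0("class", seq_len(nrow(confusion)))
  d <- diag(confusion)
  colsum <- colSums(confusion)
  rowsum <- rowSums(confusion)
  if (any(colsum == 0))
    warning("zero column sum: precision undefined for ",
            paste(cls[colsum == 0], collapse = ", "), call. = FALSE)
  precision <- 100 * d / colsum           # NaN where colsum == 0
  recall <- 100 * d / rowsum
  f <- 2 * precision * recall / (precision + recall)
  f[is.nan(precision) | is.nan(recall)] <- NaN
  f[!is.nan(f) & (precision + recall) == 0] <- NaN
  structure(
    list(confusion = confusion,
         precision = stats::setNames(precision, cls),
         recall = stats::setNames(recall, cls),
         f_measure = stats::setNames(f, cls),
         accuracy = 100 * sum(d) / total,
         support = stats::setNames(rowsum, cls)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Confusion matrix (rows = actual, columns = predicted):\n")
  print(x$confusion)
  tab <- data.frame(
    precision = round(x$precision, 1),
    recall = round(x$recall, 1),
    f_measure = round(x$f_measure, 1),
    support = x$support)
  cat("\nPer-class metrics (%):\n")
  print(tab)
  cat(sprintf("\nAccuracy: %.1f%%\n", x$accuracy))
  invisible(x)
}

#' Collapse a 3-class confusion matrix to stance-vs-neutral
#'
#' Merges the antivaccine and provaccine categories (rows and columns) of
#' a 3x3 confusion matrix in anti/pro/neutral order into a single
#' "pro_or_anti" category against "neutral".
#'
#' @param confusion 3x3 matrix, class order anti/pro/neutral.
#' @return 2x2 matrix with classes `pro_or_anti`, `neutral`.
#' @export
collapse_binary <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(3L, 3L)))
    stopf("collapse_binary() expects a 3x3 confusion matrix")
  out <- matrix(c(sum(confusion[1:2, 1:2]), sum(confusion[1:2, 3]),
                  sum(confusion[3, 1:2]), confusion[3, 3]),
                nrow = 2L, byrow = TRUE,
                dimnames = list(actual = c("pro_or_anti", "neutral"),
                                predicted = c("pro_or_anti", "neutral")))
  out
}
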