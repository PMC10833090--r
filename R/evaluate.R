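#' Confusion matrix and classification metrics
#'
#' Builds the square confusion matrix (rows = true labels, columns =
#' predicted labels) over an ordered label set and derives per-class
#' precision \eqn{TP/(TP+FP)}, recall \eqn{TP/(TP+FN)}, their harmonic
#' mean \eqn{F_1}, and support, plus overall accuracy, the unweighted
#' macro average and the support-weighted average. Metrics with a zero
#' denominator are reported as 0 and the affected class/metric pairs are
#' listed in the \code{zero_denominator} element.
#'
#' @param truth vector of true labels.
#' @param predicted vector of predicted labels (same length).
#' @param label_order ordered label set; defaults to the sorted union of
#'   observed labels.
#' @return List with elements \code{confusion} (integer matrix),
#'   \code{metrics} (data.frame: class, precision, recall, f1, support),
#'   \code{accuracy}, \code{macro} and \code{weighted} (named numeric
#'   vectors of precision/recall/f1), and \code{zero_denominator}.
#' @examples
#' ev <- evaluateClassifier(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' ev$accuracy  # 0.75
#' @export
evaluateClassifier <- function(truth, predicted, label_order = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  if (is.null(label_order))
    label_order <- sort(unique(c(truth, predicted)), method = "radix")
  extra <- setdiff(unique(c(truth, predicted)), label_order)
  if (length(extra))
    stop("labels outside label_order: ", paste(extra, collapse = ", "))
  tf <- factor(truth, levels = label_order)
  pf <- factor(predicted, levels = label_order)
  confusion <- table(truth = tf, predicted = pf)

  zero <- character(0)
  rows <- lapply(label_order, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    precision <- if (tp + fp == 0) {
      zero <<- c(zero, paste0(cl, ":precision")); 0
    } else tp / (tp + fp)
    recall <- if (tp + fn == 0) {
      zero <<- c(zero, paste0(cl, ":recall")); 0
    } else tp / (tp + fn)
    f1 <- if (precision + recall == 0) {
      zero <<- c(zero, paste0(cl, ":f1")); 0
    } else 2 * precision * recall / (precision + recall)
    data.frame(class = cl, precision = precision, recall = recall,
               f1 = f1, support = as.integer(sum(confusion[cl, ])),
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  n <- length(truth)
  wts <- metrics$support / n
  summarize <- function(w) c(
    precision = sum(w * metrics$precision),
    recall = sum(w * metrics$recall),
    f1 = sum(w * metrics$f1))
  list(confusion = unclass(confusion),
       metrics = metrics,
       accuracy = sum(diag(confusion)) / n,
       macro = summarize(rep(1 / nrow(metrics), nrow(metrics))),
       weighted = summarize(wts),
       zero_denominator = zero)
}

#' Write a metrics report as CSV
#'
#' Emits the per-class table followed by the accuracy, macro-average and
#' weighted-average rows, mirroring the standard classification-report
#' layout (Precision, Recall, F1-score, Support).
#'
#' @param report list from [evaluateClassifier()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  m <- report$metrics
  total <- sum(m$support)
  out <- rbind(
    data.frame(measure = m$class, precision = m$precision,
               recall = m$recall, f1_score = m$f1, support = m$support),
    data.frame(measure = "accuracy", precision = NA, recall = NA,
               f1_score = report$accuracy, support = total),
    data.frame(measure = "macro_average",
               precision = report$macro[["precision"]],
               recall = report$macro[["recall"]],
               f1_score = report$macro[["f1"]], support = total),
    data.frame(measure = "weighted_average",
               precision = report$weighted[["precision"]],
               recall = report$weighted[["recall"]],
               f1_score = report$weighted[["f1"]], support = total))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits document indices by label so each class appears in both halves
#' in (approximately) the global proportion.
#'
#' @param labels per-document labels.
#' @param test_frac fraction held out for testing.
#' @param seed RNG seed.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(labels, test_frac = 0.3, seed = 1L) {
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(test_frac * length(idx)))
    test <- c(test, sample(idx, min(n_test, length(idx))))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}
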