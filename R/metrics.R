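#' Class-wise precision and recall from predictions
#'
#' Per class c: `TP = #(pred = c & truth = c)`, `FP = #(pred = c & truth != c)`,
#' `FN = #(pred != c & truth = c)`; `precision = TP / (TP + FP)` and
#' `recall = TP / (TP + FN)`. A class never predicted reports precision 0 with
#' the `zero_predicted` flag set. Weighted averages are support-weighted means
#' across classes.
#'
#' @param truth true labels (factor or character).
#' @param pred predicted labels.
#' @param labels class levels; defaults to the union of levels found.
#' @return an object of class `class_metrics`: `table` (per-class data frame),
#'   `confusion` (truth x pred matrix), `weighted_precision`,
#'   `weighted_recall`, `accuracy`, `n`.
#' @examples
#' m <- class_metrics(c("A", "A", "B"), c("A", "B", "B"))
#' m$table
#' @export
class_metrics <- function(truth, pred, labels = NULL) {
  if (is.null(labels))
    labels <- union(levels(factor(truth)), levels(factor(pred)))
  truth <- factor(truth, levels = labels)
  pred <- factor(pred, levels = labels)
  if (length(truth) == 0)
    stop_cecg("empty test set", "cecg_input_error")
  if (length(truth) != length(pred))
    stop_cecg("truth and pred must have equal length", "cecg_input_error")
  conf <- table(truth = truth, pred = pred)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  support <- rowSums(conf)
  zero_pred <- (tp + fp) == 0
  precision <- ifelse(zero_pred, 0, tp / (tp + fp))
  recall <- ifelse(support == 0, NA_real_, tp / (tp + fn))
  tab <- data.frame(class = labels, tp = as.integer(tp), fp = as.integer(fp),
                    fn = as.integer(fn), support = as.integer(support),
                    precision = as.numeric(precision),
                    recall = as.numeric(recall),
                    zero_predicted = as.logical(zero_pred),
                    row.names = NULL)
  w <- support / sum(support)
  structure(list(
    table = tab, confusion = unclass(conf),
    weighted_precision = sum(w * precision),
    weighted_recall = sum(w * ifelse(is.na(recall), 0, recall)),
    accuracy = sum(tp) / length(truth), n = length(truth)
  ), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Class metrics on %d segments (accuracy %.3f)\n", x$n, x$accuracy))
  tab <- x$table
  tab$precision <- round(tab$precision, digits)
  tab$recall <- round(tab$recall, digits)
  print(tab[, c("class", "support", "precision", "recall")], row.names = FALSE)
  cat(sprintf("  weighted precision %.3f, weighted recall %.3f\n",
              x$weighted_precision, x$weighted_recall))
  invisible(x)
}

#' Evaluate a fitted classifier on a labeled test set
#'
#' Predicted class is the argmax of the softmax output; counts are accumulated
#' per class and summarized as precision/recall.
#'
#' @param model a [cnn_fit()] model.
#' @param x matrix of test segments (one per row).
#' @param y true labels.
#' @return a [class_metrics()] object.
#' @export
evaluate <- function(model, x, y) {
  stopifnot(inherits(model, "cecg_cnn"))
  if (nrow(x) == 0) stop_cecg("empty test set", "cecg_input_error")
  pred <- predict(model, x, type = "class")
  class_metrics(factor(y, levels = model$label_map), pred,
                labels = model$label_map)
}
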