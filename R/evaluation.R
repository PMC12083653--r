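#' Confusion matrix
#'
#' Square count matrix with gold classes as rows and predicted classes as
#' columns.
#'
#' @param gold,pred Aligned label vectors; every label must be in `classes`.
#' @param classes Class list; defaults to [MARITAL_LEVELS] restricted and
#'   ordered to the labels present.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(gold, pred, classes = NULL) {
  if (length(gold) != length(pred)) {
    stop("gold and pred must be aligned", call. = FALSE)
  }
  if (is.null(classes)) {
    present <- unique(c(gold, pred))
    classes <- if (all(present %in% MARITAL_LEVELS)) {
      MARITAL_LEVELS[MARITAL_LEVELS %in% present]
    } else {
      sort(present)
    }
  }
  bad <- setdiff(unique(c(gold, pred)), classes)
  if (length(bad) > 0) {
    stop(sprintf("labels outside the class list: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cm <- table(factor(gold, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(gold = classes, pred = classes))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Per-class precision, recall, F1 and support
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN), F1 their harmonic
#' mean. A zero denominator yields 0 with the corresponding `*_defined` flag
#' set to `FALSE` (e.g. a class that is never predicted has undefined,
#' reported-as-0 precision).
#'
#' @param cm A [confusion()] matrix.
#' @return Data.frame with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `support`, `n_predicted`, `precision_defined`, `recall_defined`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  classes <- rownames(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  n_pred <- colSums(cm)
  precision <- ifelse(n_pred > 0, tp / n_pred, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(
    class = classes,
    precision = as.numeric(precision), recall = as.numeric(recall),
    f1 = as.numeric(f1),
    support = as.integer(support), n_predicted = as.integer(n_pred),
    precision_defined = n_pred > 0, recall_defined = support > 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Macro, weighted and micro (accuracy) aggregation
#'
#' Macro metrics are unweighted means over classes; by default classes with
#' zero gold support are excluded from macro averaging (they remain in the
#' per-class table, flagged) so that empty classes cannot distort the macro
#' score — set `include_zero_support = TRUE` for the alternative convention.
#' Weighted metrics are support-weighted means; weighted recall equals the
#' micro accuracy identically.
#'
#' @param pcm A [per_class_metrics()] data.frame.
#' @param cm The matching [confusion()] matrix (for the accuracy numerator).
#' @param include_zero_support Include zero-support classes in macro means.
#' @return Named list: `macro_precision`, `macro_recall`, `macro_f1`,
#'   `weighted_precision`, `weighted_recall`, `weighted_f1`, `accuracy`, `n`.
#' @export
aggregate_metrics <- function(pcm, cm, include_zero_support = FALSE) {
  total <- sum(cm)
  keep <- if (include_zero_support) rep(TRUE, nrow(pcm)) else pcm$support > 0
  w <- pcm$support / sum(pcm$support)
  list(
    macro_precision = mean(pcm$precision[keep]),
    macro_recall = mean(pcm$recall[keep]),
    macro_f1 = mean(pcm$f1[keep]),
    weighted_precision = sum(w * pcm$precision),
    weighted_recall = sum(w * pcm$recall),
    weighted_f1 = sum(w * pcm$f1),
    accuracy = sum(diag(cm)) / total,
    n = total
  )
}

#' Full multiclass evaluation report
#'
#' @inheritParams confusion
#' @inheritParams aggregate_metrics
#' @return List of class `evaluation_report`: `per_class` (data.frame),
#'   the aggregate fields of [aggregate_metrics()], and `confusion`.
#' @export
evaluate_labels <- function(gold, pred, classes = NULL,
                            include_zero_support = FALSE) {
  cm <- confusion(gold, pred, classes)
  pcm <- per_class_metrics(cm)
  agg <- aggregate_metrics(pcm, cm, include_zero_support)
  structure(c(list(per_class = pcm, confusion = cm), agg),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation over %d notes: accuracy %.4f | macro P/R/F1 %.4f/%.4f/%.4f | weighted P/R/F1 %.4f/%.4f/%.4f\n",
    x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
    x$weighted_precision, x$weighted_recall, x$weighted_f1
  ))
  print(x$per_class, ...)
  invisible(x)
}
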