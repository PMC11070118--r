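#' Confusion matrix
#'
#' K x K counts with rows indexing the true class and columns the predicted
#' class, in `class_order`.
#'
#' @param truth True labels.
#' @param predicted Predicted labels, same length.
#' @param class_order Label vocabulary (default [tissue_classes()]).
#' @return An integer matrix of class `confusion_matrix`.
#' @export
#' @examples
#' cm <- confusion_matrix(c("liver", "lung"), c("liver", "liver"),
#'                        class_order = c("liver", "lung"))
#' cm
confusion_matrix <- function(truth, predicted, class_order = tissue_classes()) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  ns_assert(length(truth) == length(predicted),
            "truth and predicted differ in length", "argument_error")
  bad <- setdiff(unique(c(truth, predicted)), class_order)
  if (length(bad))
    ns_stop(paste0("label(s) outside class_order: ", paste(bad, collapse = ", ")),
            "argument_error")
  tt <- table(factor(truth, levels = class_order),
              factor(predicted, levels = class_order))
  m <- matrix(as.integer(tt), nrow = length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Build a confusion matrix directly from counts
#'
#' @param counts Square numeric matrix of counts, rows = true class.
#' @param class_order Labels for rows/columns.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, class_order = rownames(counts)) {
  counts <- as.matrix(counts)
  ns_assert(nrow(counts) == ncol(counts) && nrow(counts) == length(class_order),
            "counts must be square and match class_order", "argument_error")
  ns_assert(all(counts >= 0) && all(counts == round(counts)),
            "counts must be nonnegative integers", "argument_error")
  m <- matrix(as.integer(counts), nrow = nrow(counts),
              dimnames = list(true = class_order, predicted = class_order))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d classes, %d samples; rows = true)\n",
              nrow(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Per-class and macro-averaged performance statistics
#'
#' For each class `c`, one-vs-rest: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1 (harmonic mean of precision
#' and sensitivity). Macro averages are unweighted means over all classes
#' (ambient included); overall accuracy is `trace/total`. Precision is
#' defined as 0 when a class is never predicted (`TP+FP = 0`); such classes
#' are listed in the `flagged` field.
#'
#' @param cm A `confusion_matrix` with at least one sample.
#' @return An object of class `class_metrics`: list with `table` (per-class
#'   data frame), `macro` (named vector), `accuracy`, `flagged`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  ns_assert(total > 0, "confusion matrix is empty", "argument_error")
  K <- nrow(cm)
  cls <- rownames(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  flagged <- cls[tp + fp == 0]
  f1 <- ifelse(!is.na(sens) & (prec + sens) > 0,
               2 * prec * sens / (prec + sens), 0)
  tab <- data.frame(class = cls, sensitivity = sens, specificity = spec,
                    precision = prec, f1 = f1, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(
    table = tab,
    macro = c(sensitivity = mean(sens), specificity = mean(spec),
              precision = mean(prec), f1 = mean(f1)),
    accuracy = sum(tp) / total,
    flagged = flagged), class = "class_metrics")
}

#' @export
as.data.frame.class_metrics <- function(x, ...) {
  rbind(x$table,
        data.frame(class = "macro_average",
                   sensitivity = x$macro[["sensitivity"]],
                   specificity = x$macro[["specificity"]],
                   precision = x$macro[["precision"]],
                   f1 = x$macro[["f1"]]))
}

#' @export
print.class_metrics <- function(x, digits = 3, ...) {
  tab <- as.data.frame(x)
  tab[-1] <- lapply(tab[-1], round_half_up, digits = digits)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("Overall accuracy: %s\n", format(round_half_up(x$accuracy, digits))))
  if (length(x$flagged))
    cat("Never-predicted class(es), precision set to 0:",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
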