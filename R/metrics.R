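# Figures of merit on the percent scale:
#   accuracy    = (TP + TN) / (TP + FP + TN + FN) * 100
#   sensitivity = TP / (TP + FN) * 100
#   specificity = TN / (TN + FP) * 100
# Multiclass sensitivity/specificity are computed one-vs-rest per class.
# Undefined ratios (empty denominator) are reported as NA, never as 0 or 100.

#' Confusion matrix
#'
#' @param y_true True class labels.
#' @param y_pred Predicted class labels; every value must appear in
#'   `class_order`.
#' @param class_order Class labels in display order; defaults to
#'   first-appearance order of `y_true`.
#' @return K x K integer table, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, class_order = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (is.null(class_order)) class_order <- unique(y_true)
  unknown <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(unknown) > 0L)
    stop("labels not in class_order: ", paste(unknown, collapse = ", "))
  table(true = factor(y_true, levels = class_order),
        predicted = factor(y_pred, levels = class_order))
}

#' One-vs-rest confusion counts
#'
#' Collapses a confusion matrix to TP/TN/FP/FN with `positive_class` taken as
#' positive and every other class as negative.
#'
#' @param cm A K x K confusion matrix from [confusion_matrix()].
#' @param positive_class The class treated as positive.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`, `positive_class`.
#' @export
confusion_counts <- function(cm, positive_class) {
  cls <- rownames(cm)
  if (!positive_class %in% cls) stop("unknown class: ", positive_class)
  i <- match(positive_class, cls)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  structure(list(TP = as.integer(tp), TN = as.integer(tn),
                 FP = as.integer(fp), FN = as.integer(fn),
                 positive_class = positive_class),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity (percent)
#'
#' @param cc A `confusion_counts` object (or a list with fields TP, TN, FP,
#'   FN).
#' @return Percent value in `[0, 100]`; `sensitivity`/`specificity` return
#'   `NA` when their denominator is empty (no positives / no negatives
#'   evaluated).
#' @export
accuracy <- function(cc) {
  tot <- cc$TP + cc$FP + cc$TN + cc$FN
  if (tot == 0) stop("no evaluated samples: accuracy undefined")
  (cc$TP + cc$TN) / tot * 100
}

#' @rdname accuracy
#' @export
sensitivity <- function(cc) {
  if (cc$TP + cc$FN == 0) return(NA_real_)
  cc$TP / (cc$TP + cc$FN) * 100
}

#' @rdname accuracy
#' @export
specificity <- function(cc) {
  if (cc$TN + cc$FP == 0) return(NA_real_)
  cc$TN / (cc$TN + cc$FP) * 100
}

#' Full evaluation report
#'
#' Overall accuracy is the total fraction correct (equal to the binary
#' accuracy formula in the two-class case); per-class sensitivity and
#' specificity are one-vs-rest.
#'
#' @inheritParams confusion_matrix
#' @return An object of class `evaluation_report`: `accuracy` (percent),
#'   `sensitivity` and `specificity` (named per-class percent vectors),
#'   `confusion` (K x K table), `n` evaluated samples.
#' @export
evaluation_report <- function(y_true, y_pred, class_order = NULL) {
  cm <- confusion_matrix(y_true, y_pred, class_order)
  cls <- rownames(cm)
  sens <- spec <- stats::setNames(numeric(length(cls)), cls)
  for (k in cls) {
    cc <- confusion_counts(cm, k)
    sens[k] <- sensitivity(cc)
    spec[k] <- specificity(cc)
  }
  structure(list(accuracy = sum(diag(cm)) / sum(cm) * 100,
                 sensitivity = sens, specificity = spec,
                 confusion = cm, n = sum(cm)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.2f%% (n = %d)\n", x$accuracy, x$n))
  fmt <- function(v) ifelse(is.na(v), "n/a", sprintf("%.2f", v))
  tab <- data.frame(Class = names(x$sensitivity),
                    `Sensitivity (%)` = fmt(x$sensitivity),
                    `Specificity (%)` = fmt(x$specificity),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(
    list(accuracy = report$accuracy,
         sensitivity = as.list(report$sensitivity),
         specificity = as.list(report$specificity),
         confusion = list(classes = rownames(report$confusion),
                          counts = unclass(unname(report$confusion))),
         n = report$n),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
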