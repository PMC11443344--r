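#' Confusion matrix for the four injury grades
#'
#' Tallies actual-vs-predicted counts with rows as the actual class and
#' columns as the predicted class, in grade order A-D.
#'
#' @param y_true,y_pred equal-length vectors of labels in `A`-`D`
#'   (character or factor).
#' @return 4 x 4 integer matrix with dimnames `actual` x `predicted`.
#' @export
confusionCounts <- function(y_true, y_pred) {
  yt <- as.character(y_true); yp <- as.character(y_pred)
  if (length(yt) != length(yp)) stop("label vectors differ in length")
  if (!all(c(yt, yp) %in% gradeLabels())) stop("unknown label")
  tab <- table(factor(yt, levels = gradeLabels()),
               factor(yp, levels = gradeLabels()))
  m <- matrix(as.integer(tab), 4, 4,
              dimnames = list(actual = gradeLabels(),
                              predicted = gradeLabels()))
  m
}

#' Per-class precision, recall and F1 (percent)
#'
#' One-vs-rest per class `c`: `TP = cm[c, c]`, `FP` the rest of column `c`,
#' `FN` the rest of row `c`; `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, `F1` their harmonic mean, all in percent.
#' A class never predicted gets precision 0 with a warning; `F1 = 0` when
#' precision + recall is 0 (deterministic totals for degenerate columns).
#'
#' @param cm 4 x 4 confusion matrix, rows actual, columns predicted.
#' @return data.frame: `class`, `precision`, `recall`, `f1` (percent).
#' @export
classMetrics <- function(cm) {
  cm <- validateCM(cm)
  out <- lapply(seq_len(nrow(cm)), function(c0) {
    tp <- cm[c0, c0]
    fp <- sum(cm[, c0]) - tp
    fn <- sum(cm[c0, ]) - tp
    prec <- if (tp + fp == 0) {
      warning(sprintf("class %s never predicted; precision = 0",
                      rownames(cm)[c0]))
      0
    } else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = rownames(cm)[c0], precision = 100 * prec,
               recall = 100 * rec, f1 = 100 * f1)
  })
  do.call(rbind, out)
}

#' Overall accuracy and macro-averaged metrics (percent)
#'
#' Accuracy is `100 * trace / total` (the multiclass generalization of the
#' binary (TP + TN) / all form); macro precision, recall and F1 are
#' unweighted means of the per-class values from [classMetrics()].
#' Micro and class-frequency-weighted averages are available via
#' `average`, but macro is the default reporting convention here.
#'
#' @param cm 4 x 4 confusion matrix, rows actual, columns predicted.
#' @param average one of `"macro"`, `"micro"`, `"weighted"`.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`
#'   (percent).
#' @export
macroMetrics <- function(cm, average = c("macro", "micro", "weighted")) {
  average <- match.arg(average)
  cm <- validateCM(cm)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  per <- classMetrics(cm)
  if (average == "macro") {
    w <- rep(1 / nrow(cm), nrow(cm))
  } else if (average == "weighted") {
    w <- rowSums(cm) / sum(cm)
  } else {
    # micro: pooled one-vs-rest counts; for single-label multiclass all
    # three collapse to accuracy
    return(c(accuracy = acc, precision = acc, recall = acc, f1 = acc))
  }
  c(accuracy = acc,
    precision = sum(w * per$precision),
    recall = sum(w * per$recall),
    f1 = sum(w * per$f1))
}

validateCM <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  if (is.null(rownames(cm)))
    dimnames(cm) <- list(actual = gradeLabels()[seq_len(nrow(cm))],
                         predicted = gradeLabels()[seq_len(ncol(cm))])
  cm
}

#' Full metric report
#'
#' Bundles the confusion matrix, per-class metrics, macro metrics and the
#' per-class F1 curve data into one serializable object. Display values are
#' rounded half-up to 2 decimals (percent scale); the stored values are
#' unrounded.
#'
#' @param cm 4 x 4 confusion matrix.
#' @param metadata optional named list recorded verbatim in the report.
#' @return List of class `metric_report` with `confusion`, `per_class`,
#'   `macro`, `f1_curve`, `metadata`.
#' @export
metricReport <- function(cm, metadata = list()) {
  cm <- validateCM(cm)
  per <- classMetrics(cm)
  structure(
    list(confusion = cm, per_class = per, macro = macroMetrics(cm),
         f1_curve = data.frame(class = per$class, f1 = per$f1),
         metadata = metadata),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report\n")
  print(x$confusion)
  m <- roundHalfUp(x$macro, 2)
  cat(sprintf("accuracy %.2f | macro precision %.2f | recall %.2f | F1 %.2f\n",
              m[["accuracy"]], m[["precision"]], m[["recall"]], m[["f1"]]))
  invisible(x)
}

#' Serialize / parse a metric report
#'
#' `writeMetricReport()` writes the JSON report plus, optionally, the
#' confusion matrix and per-class F1 curve as CSV; `readMetricReport()`
#' round-trips the JSON back into a `metric_report`.
#'
#' @param report a `metric_report` from [metricReport()].
#' @param json_path output JSON path.
#' @param confusion_csv,f1_csv optional CSV paths.
#' @param path JSON path to read.
#' @return The JSON path (write) or the parsed `metric_report` (read).
#' @export
writeMetricReport <- function(report, json_path, confusion_csv = NULL,
                              f1_csv = NULL) {
  stopifnot(inherits(report, "metric_report"))
  payload <- list(
    confusion = unclass(unname(report$confusion)),
    labels = rownames(report$confusion),
    per_class = report$per_class,
    macro = as.list(report$macro),
    f1_curve = report$f1_curve,
    metadata = report$metadata
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusion_csv))
    utils::write.csv(report$confusion, confusion_csv)
  if (!is.null(f1_csv))
    utils::write.csv(report$f1_curve, f1_csv, row.names = FALSE)
  invisible(json_path)
}

#' @rdname writeMetricReport
#' @export
readMetricReport <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- as.matrix(p$confusion)
  storage.mode(cm) <- "integer"
  dimnames(cm) <- list(actual = p$labels, predicted = p$labels)
  metricReport(cm, metadata = as.list(p$metadata))
}
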