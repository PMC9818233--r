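# Metrics engine: 2x2 confusion matrices over {NORMAL, PVC} with PVC as
# the positive class, per-class precision/recall/F1/specificity, overall
# accuracy, macro averages and balanced accuracy.

#' Build a confusion matrix from true and predicted labels
#'
#' @param true_labels,predicted_labels vectors (factor or character)
#'   with values in NORMAL/PVC, equal length.
#' @return object of class `pvc_confusion`: a 2x2 integer matrix, rows =
#'   true label, columns = predicted label.
#' @export
confusion <- function(true_labels, predicted_labels) {
  t_ <- as.character(true_labels)
  p_ <- as.character(predicted_labels)
  if (length(t_) != length(p_)) stop("label vectors differ in length")
  bad <- unique(c(t_, p_))
  bad <- bad[!bad %in% c("NORMAL", "PVC")]
  if (length(bad) > 0) {
    stop("labels outside {NORMAL, PVC}: ", paste(bad, collapse = ", "))
  }
  m <- table(factor(t_, levels = c("NORMAL", "PVC")),
             factor(p_, levels = c("NORMAL", "PVC")))
  cm <- matrix(as.integer(m), nrow = 2,
               dimnames = list(true = c("NORMAL", "PVC"),
                               predicted = c("NORMAL", "PVC")))
  structure(cm, class = c("pvc_confusion", "matrix"))
}

#' Build a confusion matrix directly from counts
#'
#' Counts are indexed by (true, predicted): `nn` true NORMAL predicted
#' NORMAL, `nv` true NORMAL predicted PVC, `vn` true PVC predicted
#' NORMAL, `vv` true PVC predicted PVC. With PVC the positive class,
#' TP = `vv`, FP = `nv`, FN = `vn`, TN = `nn`.
#'
#' @param nn,nv,vn,vv cell counts.
#' @return a `pvc_confusion`.
#' @export
confusion_from_counts <- function(nn, nv, vn, vv) {
  stopifnot(nn >= 0, nv >= 0, vn >= 0, vv >= 0)
  cm <- matrix(as.numeric(c(nn, vn, nv, vv)), nrow = 2,
               dimnames = list(true = c("NORMAL", "PVC"),
                               predicted = c("NORMAL", "PVC")))
  structure(cm, class = c("pvc_confusion", "matrix"))
}

#' @export
print.pvc_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Sum confusion matrices (fold aggregation)
#' @param ... `pvc_confusion` objects.
#' @export
sum_confusions <- function(...) {
  ms <- list(...)
  if (length(ms) == 1 && is.list(ms[[1]]) && !inherits(ms[[1]], "pvc_confusion")) {
    ms <- ms[[1]]
  }
  out <- Reduce(`+`, lapply(ms, unclass))
  structure(out, class = c("pvc_confusion", "matrix"))
}

.safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Compute the full metric set from a confusion matrix
#'
#' Per class (each class in turn taken as positive): precision
#' TP/(TP+FP), recall TP/(TP+FN), F1 = 2 x precision x recall /
#' (precision + recall), specificity TN/(TN+FP). Overall accuracy is
#' (TP+TN)/total; macro averages are unweighted means over the two
#' classes; balanced accuracy is (recall + specificity)/2 with PVC as
#' the positive class, computed from the raw counts (equivalently, the
#' macro-average recall). In the binary case the specificity of one
#' class equals the recall of the other. Metrics with a zero denominator
#' are reported as `NA` and flagged in `$undefined`, never coerced to 0.
#'
#' @param cm a `pvc_confusion`.
#' @return object of class `metrics_report`: list with `per_class`
#'   (data.frame), `accuracy`, `macro` (named vector), and
#'   `balanced_accuracy`, all as proportions in `[0, 1]`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "pvc_confusion"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  per_class <- do.call(rbind, lapply(c("NORMAL", "PVC"), function(pos) {
    neg <- setdiff(c("NORMAL", "PVC"), pos)
    tp <- cm[pos, pos]; fp <- cm[neg, pos]
    fn <- cm[pos, neg]; tn <- cm[neg, neg]
    precision <- .safe_div(tp, tp + fp)
    recall <- .safe_div(tp, tp + fn)
    f1 <- .safe_div(2 * tp, 2 * tp + fp + fn)
    specificity <- .safe_div(tn, tn + fp)
    data.frame(class = pos, precision = precision, recall = recall,
               f1 = f1, specificity = specificity,
               stringsAsFactors = FALSE)
  }))
  accuracy <- (cm["NORMAL", "NORMAL"] + cm["PVC", "PVC"]) / total
  macro <- c(precision = mean(per_class$precision),
             recall = mean(per_class$recall),
             f1 = mean(per_class$f1),
             specificity = mean(per_class$specificity))
  bal <- mean(c(per_class$recall[per_class$class == "PVC"],
                per_class$specificity[per_class$class == "PVC"]))
  undefined <- c(per_class$class[!stats::complete.cases(per_class)])
  structure(list(per_class = per_class, accuracy = accuracy, macro = macro,
                 balanced_accuracy = bal,
                 undefined = undefined, confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "  --  ",
                            sprintf("%6.2f", round_half_up(100 * v, 2)))
  cat("Metrics (%):\n")
  cat(sprintf("  %-8s %9s %9s %9s %11s\n",
              "class", "precision", "recall", "F1", "specificity"))
  for (i in seq_len(nrow(x$per_class))) {
    r <- x$per_class[i, ]
    cat(sprintf("  %-8s %9s %9s %9s %11s\n", r$class, pct(r$precision),
                pct(r$recall), pct(r$f1), pct(r$specificity)))
  }
  cat(sprintf("  %-8s %9s %9s %9s %11s\n", "macro", pct(x$macro["precision"]),
              pct(x$macro["recall"]), pct(x$macro["f1"]),
              pct(x$macro["specificity"])))
  cat(sprintf("  accuracy: %s   balanced accuracy: %s\n",
              trimws(pct(x$accuracy)), trimws(pct(x$balanced_accuracy))))
  if (length(x$undefined) > 0) {
    cat("  undefined (zero-denominator) metrics for class(es):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a metrics report to a data.frame (CSV-friendly)
#' @param report a `metrics_report`.
#' @param experiment optional experiment tag column.
#' @export
report_as_table <- function(report, experiment = NA_character_) {
  pc <- report$per_class
  rows <- rbind(
    data.frame(experiment = experiment, class = pc$class,
               metric = rep(c("precision", "recall", "f1", "specificity"),
                            each = nrow(pc)),
               value = c(pc$precision, pc$recall, pc$f1, pc$specificity)),
    data.frame(experiment = experiment, class = "macro",
               metric = names(report$macro),
               value = as.numeric(report$macro)),
    data.frame(experiment = experiment, class = "overall",
               metric = c("accuracy", "balanced_accuracy"),
               value = c(report$accuracy, report$balanced_accuracy)))
  rownames(rows) <- NULL
  rows
}
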