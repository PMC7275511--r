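as_class_index <- function(x, labels) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    ix <- unname(labels$index[x])
    if (anyNA(ix)) stop("unknown class name(s): ",
                        paste(unique(x[is.na(ix)]), collapse = ", "),
                        call. = FALSE)
    return(as.integer(ix))
  }
  ix <- as.integer(x)
  if (any(ix < 1L | ix > labels$n_classes))
    stop("class index out of range", call. = FALSE)
  ix
}

#' One-vs-rest confusion counts
#'
#' For each class, a document with that label is a positive example and a
#' document with any other label is a negative example; TP/FP/FN/TN are
#' tallied accordingly.
#'
#' @param truth,predicted Class names or indices, equal length.
#' @param labels A [label_set()].
#' @return Object of class \code{"fcnbla_confusion"}: a C x 4 count matrix
#'   plus the multiclass cross-tabulation.
#' @export
confusion_counts <- function(truth, predicted, labels) {
  ti <- as_class_index(truth, labels)
  pi_ <- as_class_index(predicted, labels)
  if (length(ti) != length(pi_))
    stop("truth and predicted have different lengths", call. = FALSE)
  n <- length(ti)
  C <- labels$n_classes
  cross <- table(factor(ti, levels = seq_len(C)),
                 factor(pi_, levels = seq_len(C)))
  tp <- diag(cross)
  fp <- colSums(cross) - tp
  fn <- rowSums(cross) - tp
  tn <- n - tp - fp - fn
  counts <- cbind(TP = as.integer(tp), FP = as.integer(fp),
                  FN = as.integer(fn), TN = as.integer(tn))
  rownames(counts) <- labels$classes
  structure(list(counts = counts, cross = cross, n = n, labels = labels),
            class = "fcnbla_confusion")
}

#' @export
print.fcnbla_confusion <- function(x, ...) {
  cat("One-vs-rest confusion counts (", x$n, " documents)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Accuracy and macro-averaged precision / recall / F-score
#'
#' Per class, precision = TP / (TP + FP), recall = TP / (TP + FN), and the
#' F-score is their harmonic mean; a zero denominator yields 0. The macro
#' metrics are unweighted means over the C classes, making the report
#' sensitive to minority-class performance under imbalance. Accuracy is the
#' fraction of correctly classified documents (equivalently, one class's
#' one-vs-rest (TP + TN) / n).
#'
#' @param x An \code{fcnbla_confusion} from [confusion_counts()], or a truth
#'   vector (then \code{predicted} and \code{labels} are required).
#' @param predicted,labels See [confusion_counts()].
#' @return Object of class \code{"fcnbla_report"}: \code{per_class} data
#'   frame and scalars \code{precision_macro}, \code{recall_macro},
#'   \code{f_score_macro}, \code{accuracy}.
#' @export
evaluation_report <- function(x, predicted = NULL, labels = NULL) {
  if (!inherits(x, "fcnbla_confusion"))
    x <- confusion_counts(x, predicted, labels)
  cc <- x$counts
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(cc[, "TP"], cc[, "TP"] + cc[, "FP"])
  recall <- safe_div(cc[, "TP"], cc[, "TP"] + cc[, "FN"])
  f <- safe_div(2 * precision * recall, precision + recall)
  per_class <- data.frame(class = rownames(cc),
                          n = as.integer(cc[, "TP"] + cc[, "FN"]),
                          precision = unname(precision),
                          recall = unname(recall), f = unname(f),
                          row.names = NULL)
  structure(list(per_class = per_class,
                 precision_macro = mean(precision),
                 recall_macro = mean(recall),
                 f_score_macro = mean(f),
                 accuracy = sum(cc[, "TP"]) / x$n,
                 n = x$n),
            class = "fcnbla_report")
}

#' @export
print.fcnbla_report <- function(x, digits = 4, ...) {
  cat("Evaluation on", x$n, "documents\n\n")
  pc <- x$per_class
  pc$precision <- round(pc$precision, digits)
  pc$recall <- round(pc$recall, digits)
  pc$f <- round(pc$f, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("\n  Precision_macro %.4f  Recall_macro %.4f  F-score_macro %.4f  Accuracy %.4f\n",
              x$precision_macro, x$recall_macro, x$f_score_macro, x$accuracy))
  invisible(x)
}

#' Write an evaluation report as a machine-readable TSV
#' @param report An \code{fcnbla_report}.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  pc <- report$per_class
  macro <- data.frame(class = "MACRO", n = report$n,
                      precision = report$precision_macro,
                      recall = report$recall_macro,
                      f = report$f_score_macro)
  utils::write.table(rbind(pc, macro), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Evaluate a fitted model on labeled records
#'
#' @param object A fitted [fcnbla()] model.
#' @param records Labeled records.
#' @return An \code{fcnbla_report}.
#' @export
evaluate_records <- function(object, records) {
  truth <- vapply(records, `[[`, character(1), "label")
  pred <- predict(object, records, type = "class")
  evaluation_report(confusion_counts(truth, as.character(pred), object$labels))
}
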