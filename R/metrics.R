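#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed from ranks: the probability that a
#' randomly chosen positive sample scores higher than a randomly chosen
#' negative one, with tied scores counted 1/2.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Binary labels: logical, 0/1, or a factor whose *first* level
#'   is the positive class (consistent with the package's class-order
#'   convention).
#' @param positive Optional explicit positive-class value.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive = NULL) {
  if (is.factor(labels)) {
    pos <- if (is.null(positive)) levels(labels)[1L] else positive
    y <- labels == pos
  } else if (is.logical(labels)) {
    y <- labels
  } else {
    pos <- if (is.null(positive)) 1 else positive
    y <- labels == pos
  }
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass precision/recall/F1 report
#'
#' Per-class precision and recall are computed one-vs-rest from TP/FP/FN.
#' Macro precision and recall are unweighted means over classes; the macro F1
#' is the *harmonic mean of the macro-averaged precision and recall*,
#' `2 * P_m * R_m / (P_m + R_m)` -- deliberately distinct from the common
#' mean of per-class F1 scores. Weighted variants use the class frequencies
#' in `y_true` as weights, with the weighted F1 again the harmonic mean of
#' the weighted means. A class never predicted has undefined precision, and a
#' class absent from `y_true` has undefined recall; both are set to 0 by
#' convention (conservative).
#'
#' @param y_true,y_pred Vectors of true and predicted class labels.
#' @param class_order Optional class ordering; defaults to the union of
#'   labels in first-appearance order of `y_true`.
#' @return Object of class `aigps_eval`: list with `per_class` (data.frame of
#'   `precision`, `recall`, `f1`, `weight`), `macro_precision`,
#'   `macro_recall`, `macro_f1`, `weighted_precision`, `weighted_recall`,
#'   `weighted_f1`, `accuracy`.
#' @export
multiclass_metrics <- function(y_true, y_pred, class_order = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(class_order)) class_order <- unique(c(y_true, y_pred))
  bad <- setdiff(c(y_true, y_pred), class_order)
  if (length(bad) > 0L) {
    stop("label(s) outside class_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  nC <- length(class_order)
  prec <- rec <- w <- numeric(nC)
  for (ci in seq_len(nC)) {
    cl <- class_order[ci]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec[ci] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[ci] <- if (tp + fn > 0) tp / (tp + fn) else 0
    w[ci] <- sum(y_true == cl) / length(y_true)
  }
  hm <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0
  pm <- mean(prec); rm_ <- mean(rec)
  pw <- sum(w * prec); rw <- sum(w * rec)
  per_class <- data.frame(class = class_order, precision = prec, recall = rec,
                          f1 = mapply(hm, prec, rec), weight = w,
                          stringsAsFactors = FALSE)
  structure(list(per_class = per_class,
                 macro_precision = pm, macro_recall = rm_,
                 macro_f1 = hm(pm, rm_),
                 weighted_precision = pw, weighted_recall = rw,
                 weighted_f1 = hm(pw, rw),
                 accuracy = mean(y_true == y_pred)),
            class = "aigps_eval")
}

#' @export
print.aigps_eval <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P/R/F1 %.4f/%.4f/%.4f | weighted P/R/F1 %.4f/%.4f/%.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              x$weighted_precision, x$weighted_recall, x$weighted_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report both as JSON and as a flat one-row TSV.
#'
#' @param report An `aigps_eval` object.
#' @param path Output path stem; `.json` and `.tsv` are appended.
#' @export
write_eval_report <- function(report, path) {
  flat <- c(accuracy = report$accuracy,
            macro_precision = report$macro_precision,
            macro_recall = report$macro_recall,
            macro_f1 = report$macro_f1,
            weighted_precision = report$weighted_precision,
            weighted_recall = report$weighted_recall,
            weighted_f1 = report$weighted_f1)
  jsonlite::write_json(
    c(as.list(flat), list(per_class = report$per_class)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(as.list(flat)), paste0(path, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
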