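# Classification metric suite: accuracy, precision, recall (sensitivity),
# specificity, F1 and AUC, from confusion counts; multi-class versions are
# macro-averaged one-vs-rest. AUC is the rank (Mann-Whitney) statistic on
# probability scores, flagged NA on degenerate inputs rather than forced to
# a number.

#' Metrics from binary confusion counts
#'
#' @param tp,fp,fn,tn confusion counts.
#' @return Named list: `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1` (NA where a denominator is zero).
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = div(tp + tn, tp + fp + fn + tn),
       precision = precision, recall = recall,
       specificity = div(tn, tn + fp), f1 = f1)
}

auc_score <- function(truth01, score) {
  if (length(unique(truth01)) < 2L || length(unique(score)) < 2L)
    return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(truth01, score, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Evaluation report for a set of predictions
#'
#' Binary problems report metrics for the `positive` class (default: the
#' second factor level). Multi-class problems report accuracy plus
#' macro-averaged one-vs-rest precision/recall/specificity/F1 and macro
#' one-vs-rest AUC from the probability scores. A class absent from `truth`
#' makes the affected metrics NA and is listed in `$undefined` -- degenerate
#' metrics are flagged, never silently zeroed.
#'
#' @param truth factor of true labels.
#' @param pred factor of predicted labels (same level set).
#' @param scores optional B x K probability matrix with `colnames` equal to
#'   the class levels (needed for AUC).
#' @param positive positive class for binary problems.
#' @return An object of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `specificity`, `f1`, `auc`, `confusion` (K x K table),
#'   `per_class` counts, `undefined` (character vector of flags).
#' @export
metrics_report <- function(truth, pred, scores = NULL, positive = NULL) {
  lev <- levels(factor(truth))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  K <- length(lev)
  conf <- table(truth = truth, pred = pred)
  undefined <- character(0)
  per_class <- lapply(lev, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    c(tp = tp, fp = fp, fn = fn, tn = tn)
  })
  names(per_class) <- lev
  absent <- lev[vapply(lev, function(cl) sum(truth == cl) == 0L, logical(1))]
  if (length(absent))
    undefined <- c(undefined, paste0("class absent from truth: ",
                                     paste(absent, collapse = ", ")))
  cls_metrics <- lapply(per_class, function(ct)
    metrics_from_counts(ct["tp"], ct["fp"], ct["fn"], ct["tn"]))
  if (K == 2L) {
    if (is.null(positive)) positive <- lev[2L]
    m <- cls_metrics[[positive]]
    auc <- NA_real_
    if (!is.null(scores)) {
      auc <- auc_score(as.integer(truth == positive), scores[, positive])
      if (is.na(auc)) undefined <- c(undefined, "auc: degenerate scores")
    }
    out <- list(accuracy = m$accuracy, precision = m$precision,
                recall = m$recall, specificity = m$specificity, f1 = m$f1,
                auc = auc, averaging = paste0("binary (positive = ",
                                              positive, ")"))
  } else {
    mac <- function(field) {
      v <- vapply(cls_metrics, function(x) x[[field]], numeric(1))
      if (anyNA(v)) NA_real_ else mean(v)
    }
    auc <- NA_real_
    if (!is.null(scores)) {
      aucs <- vapply(lev, function(cl)
        auc_score(as.integer(truth == cl), scores[, cl]), numeric(1))
      if (anyNA(aucs)) undefined <- c(undefined, "auc: degenerate scores")
      else auc <- mean(aucs)
    }
    out <- list(accuracy = mean(pred == truth), precision = mac("precision"),
                recall = mac("recall"), specificity = mac("specificity"),
                f1 = mac("f1"), auc = auc,
                averaging = "macro one-vs-rest")
  }
  out$confusion <- conf
  out$per_class <- per_class
  out$undefined <- undefined
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> (", x$averaging, ")\n", sep = "")
  v <- unlist(x[c("accuracy", "precision", "recall", "specificity",
                  "f1", "auc")])
  print(round(v, 4))
  if (length(x$undefined))
    cat("flags:", paste(x$undefined, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, precision = x$precision,
             recall = x$recall, specificity = x$specificity, f1 = x$f1,
             auc = x$auc)
}
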