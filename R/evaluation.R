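## Evaluation: confusion matrix, binary and macro one-vs-rest metrics, ROC
## curves and (mean) AUC.

#' Confusion matrix over a fixed class set
#'
#' @param truth,predicted label vectors of equal length; values must belong
#'   to `classes`.
#' @param classes ordered class labels; default sorted union of observed
#'   labels.
#' @return object of class `confusion_matrix`: integer matrix
#'   `counts[true, predicted]`.
#' @export
confusion <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop_dg("truth and predicted lengths differ (%d vs %d)",
            length(truth), length(predicted), class = "dg_invalid_input")
  classes <- as.character(classes %||% sort(unique(c(truth, predicted))))
  if (!all(truth %in% classes) || !all(predicted %in% classes))
    stop_dg("labels outside the declared class set", class = "dg_invalid_input")
  cm <- table(factor(truth, classes), factor(predicted, classes))
  structure(unclass(cm), dimnames = list(truth = classes, predicted = classes),
            class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  print(unclass(x))
  invisible(x)
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warn_dg("%s undefined (0/0); reported as 0", what,
            class = "dg_zero_division")
    return(0)
  }
  num / den
}

#' Binary classification metrics from a 2x2 confusion matrix
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), F1 = harmonic mean of precision and sensitivity, accuracy =
#' (TP+TN)/total. Zero denominators yield 0 with a warning.
#'
#' @param cm a 2x2 [confusion()] matrix.
#' @param positive_class label counted as positive. The reproduction default
#'   throughout the package is NIHSS grade 0 (no drift) as positive.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `f1`, `positive_class`.
#' @export
binary_metrics <- function(cm, positive_class = rownames(cm)[1L]) {
  if (!all(dim(cm) == c(2L, 2L)))
    stop_dg("binary_metrics needs a 2x2 matrix", class = "dg_invalid_input")
  positive_class <- as.character(positive_class)
  neg <- setdiff(rownames(cm), positive_class)
  tp <- cm[positive_class, positive_class]
  fn <- cm[positive_class, neg]
  fp <- cm[neg, positive_class]
  tn <- cm[neg, neg]
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  list(accuracy = (tp + tn) / sum(cm), sensitivity = sens,
       specificity = spec, precision = prec, f1 = f1,
       positive_class = positive_class)
}

#' Macro-averaged one-vs-rest metrics from a c x c confusion matrix
#'
#' Each class is scored one-vs-rest; aggregates are unweighted (macro)
#' means. An empty truth row yields sensitivity 0 for that class with a
#' warning.
#'
#' @param cm a square [confusion()] matrix, c >= 2.
#' @return list with `accuracy`, per-class data frame `per_class`, and macro
#'   `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
multiclass_metrics <- function(cm) {
  classes <- rownames(cm)
  if (nrow(cm) != ncol(cm) || nrow(cm) < 2L)
    stop_dg("need a square confusion matrix with >= 2 classes",
            class = "dg_invalid_input")
  total <- sum(cm)
  per <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    sens <- safe_div(tp, tp + fn, sprintf("sensitivity of class %s", cl))
    spec <- safe_div(tn, tn + fp, sprintf("specificity of class %s", cl))
    prec <- safe_div(tp, tp + fp, sprintf("precision of class %s", cl))
    f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    data.frame(class = cl, sensitivity = sens, specificity = spec,
               precision = prec, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(accuracy = sum(diag(cm)) / total, per_class = per,
       sensitivity = mean(per$sensitivity), specificity = mean(per$specificity),
       precision = mean(per$precision), f1 = mean(per$f1))
}

#' ROC curve and trapezoidal AUC for a binary score
#'
#' Sweeps thresholds over the unique score values (descending); tied scores
#' step simultaneously, making the trapezoidal area equal to the
#' Mann-Whitney U statistic divided by `n_pos * n_neg` with half credit for
#' ties.
#'
#' @param scores numeric positive-class score per instance (higher = more
#'   positive).
#' @param truth binary labels.
#' @param positive_class label counted as positive (default first sorted
#'   level).
#' @return object of class `roc_curve`: list with `thresholds`, `fpr`,
#'   `tpr` (non-decreasing from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, truth, positive_class = NULL) {
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  if (length(classes) < 2L)
    stop_dg("AUC undefined: a single class present in truth",
            class = "dg_undefined_auc")
  positive_class <- as.character(positive_class %||% classes[1L])
  pos <- truth == positive_class
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores into simultaneous steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr,
                 auc = auc, positive_class = positive_class),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC %.3f (positive = %s)\n",
              length(x$fpr), x$auc, x$positive_class))
  invisible(x)
}

#' Mean one-vs-rest AUC for multiclass scores
#'
#' Computes a one-vs-rest [roc_curve()] per class using that class's score
#' column and returns the unweighted mean AUC. Classes declared in the score
#' matrix but absent from truth are excluded with a warning.
#'
#' @param scores matrix of per-class scores, columns named by class.
#' @param truth multiclass labels.
#' @return list with `mean_auc` and per-class `auc` vector.
#' @export
mean_ovr_auc <- function(scores, truth) {
  truth <- as.character(truth)
  classes <- colnames(scores)
  present <- classes %in% truth
  if (sum(present) < 2L)
    stop_dg("need >= 2 classes present in truth", class = "dg_undefined_auc")
  if (any(!present))
    warn_dg("class(es) %s absent from truth; excluded from mean AUC",
            paste(classes[!present], collapse = ", "),
            class = "dg_class_absent")
  aucs <- vapply(classes[present], function(cl) {
    roc_curve(scores[, cl], ifelse(truth == cl, cl, "rest"),
              positive_class = cl)$auc
  }, 0)
  list(mean_auc = mean(aucs), auc = aucs)
}

#' Full evaluation report for a grading result
#'
#' @param result a `grading_result` from [predict.drift_grader()].
#' @param truth true labels for the evaluated instances.
#' @param positive_class positive class for binary tasks (default the lowest
#'   grade, i.e. NIHSS 0).
#' @return object of class `evaluation_report`: list with `confusion`,
#'   `accuracy`, `sensitivity`, `specificity`, `precision`, `f1`, `auc`
#'   (binary trapezoidal or multiclass mean one-vs-rest), `per_class`
#'   (multiclass only) and `roc` (binary only).
#' @export
evaluate_grading <- function(result, truth, positive_class = NULL) {
  classes <- colnames(result$scores)
  cm <- confusion(truth, result$grade, classes = classes)
  if (length(classes) == 2L) {
    positive_class <- as.character(positive_class %||% classes[1L])
    m <- binary_metrics(cm, positive_class)
    roc <- roc_curve(result$scores[, positive_class], truth,
                     positive_class = positive_class)
    rep <- c(list(confusion = cm), m, list(auc = roc$auc, roc = roc))
  } else {
    m <- multiclass_metrics(cm)
    auc <- mean_ovr_auc(result$scores, truth)
    rep <- list(confusion = cm, accuracy = m$accuracy,
                sensitivity = m$sensitivity, specificity = m$specificity,
                precision = m$precision, f1 = m$f1,
                auc = auc$mean_auc, per_class = m$per_class,
                auc_per_class = auc$auc)
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$confusion)
  cat(sprintf(
    "accuracy %.3f | sensitivity %.3f | specificity %.3f | precision %.3f | F1 %.3f | AUC %.3f\n",
    x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1, x$auc))
  invisible(x)
}
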