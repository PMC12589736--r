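#' Multiclass confusion matrix
#'
#' `counts[i, j]` is the number of samples with true class `i` predicted
#' as class `j`; the diagonal holds the correctly classified cases.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class order; defaults to the sorted union of observed
#'   labels.
#' @return A `confusion_matrix`: integer classes-by-classes matrix with
#'   dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  classes <- classes %||% sort_c(unique(c(as.character(y_true), as.character(y_pred))))
  unknown <- setdiff(unique(c(as.character(y_true), as.character(y_pred))), classes)
  if (length(unknown)) {
    stop("labels outside the declared class order: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(true = factor(y_true, classes), predicted = factor(y_pred, classes))
  structure(unclass(as.matrix(counts)), class = "confusion_matrix")
}

#' One-vs-rest metrics for a single class
#'
#' Treating `class` as positive and the rest as negative:
#' sensitivity `TP/(TP+FN)`, accuracy `(TP+TN)/total`, precision
#' `TP/(TP+FP)`, specificity `TN/(TN+FP)`, all as percentages, plus the F1
#' score. A zero denominator yields `NA` (reported as undefined, never
#' silently 0).
#'
#' @param cm A [confusion_matrix()].
#' @param class Class name (row/column of `cm`).
#' @return One-row tibble with `class`, `tp`, `fn`, `fp`, `tn` and the
#'   metric percentages.
#' @export
per_class_metrics <- function(cm, class) {
  stopifnot(inherits(cm, "confusion_matrix"), class %in% rownames(cm))
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fn - fp
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- pct(tp, tp + fn)
  prec <- pct(tp, tp + fp)
  tibble::tibble(
    class = class, tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = sens,
    accuracy = pct(tn + tp, sum(cm)),
    precision = prec,
    specificity = pct(tn, tn + fp),
    f1 = if (is.na(sens) || is.na(prec)) NA_real_ else f1_score(prec, sens)
  )
}

#' F1 score from precision and sensitivity percentages
#'
#' Harmonic mean `2 P S / (P + S)`, on the percentage scale; 0 when both
#' inputs are 0 by convention.
#'
#' @param precision,sensitivity Percentages (>= 0).
#' @return F1 percentage.
#' @export
f1_score <- function(precision, sensitivity) {
  stopifnot(all(precision >= 0, na.rm = TRUE), all(sensitivity >= 0, na.rm = TRUE))
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' One-vs-rest ROC AUC
#'
#' Tie-corrected rank (Mann-Whitney) statistic, identical to the
#' trapezoidal area under the ROC curve over all score thresholds, and
#' invariant to strictly monotone transforms of the scores.
#'
#' @param truth Logical (or 0/1) vector: positive-class membership.
#' @param scores Numeric scores (higher means more positive).
#' @return AUC in `[0, 1]`; `NA` with a warning if only one class is
#'   present.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.logical(truth)
  stopifnot(length(truth) == length(scores))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) {
    warning("ROC AUC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)  # average ranks correct for ties
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class and macro evaluation report
#'
#' One-vs-rest AUC, sensitivity, accuracy, precision, specificity and F1
#' per class (as percentages) plus their unweighted macro averages — the
#' package's analogue of a per-lesion results table with its "Average
#' ratio" row. Overall top-1 accuracy is attached as an attribute.
#'
#' @param y_true True labels.
#' @param scores Samples-by-classes score matrix (e.g. from
#'   [predict_proba()]); predictions are the row argmax.
#' @param classes Class order; defaults to the score-matrix columns.
#' @return A `metrics_report` tibble (per-class rows + a `macro` row) with
#'   attributes `overall_accuracy` and `confusion`.
#' @export
macro_report <- function(y_true, scores, classes = colnames(scores)) {
  stopifnot(!is.null(classes), length(y_true) == nrow(scores))
  y_pred <- classes[max.col(scores[, classes, drop = FALSE], ties.method = "first")]
  cm <- confusion_matrix(y_true, y_pred, classes)
  per <- purrr::map_dfr(classes, function(cl) {
    row <- per_class_metrics(cm, cl)
    row$auc <- 100 * roc_auc(y_true == cl, scores[, cl])
    row
  })
  per <- dplyr::select(per, "class", "auc", "sensitivity", "accuracy",
                       "precision", "f1", "specificity")
  macro <- dplyr::summarise(per, class = "macro",
                            dplyr::across(-"class", ~mean(.x)))
  out <- dplyr::bind_rows(per, macro)
  structure(out, class = c("metrics_report", class(tibble::tibble())),
            overall_accuracy = 100 * mean(y_pred == as.character(y_true)),
            confusion = cm)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> overall top-1 accuracy %.2f%%\n",
              attr(x, "overall_accuracy")))
  NextMethod()
}

#' Paired t-test on per-class F1 scores
#'
#' Compares two models' class-wise F1 vectors as paired observations:
#' `Delta = mean(a - b)`, `t = Delta / (sd(a - b)/sqrt(n))` with the
#' sample (n-1) standard deviation, `df = n - 1`, and a one-sided p-value
#' for the alternative that model A scores higher. Zero-variance
#' differences give `t = Inf`, `p = 0` when `Delta != 0`, and a flagged
#' no-difference result when `Delta == 0`.
#'
#' @param f1_a,f1_b Equal-length per-class F1 vectors (percentage points),
#'   `n >= 2`.
#' @param alpha Significance level (default 0.05).
#' @return A `comparison_result`: `delta`, `t_statistic`, `df`, `p_value`,
#'   `significant`, `n_pairs`.
#' @export
paired_f1_ttest <- function(f1_a, f1_b, alpha = 0.05) {
  stopifnot(length(f1_a) == length(f1_b), length(f1_a) >= 2)
  d <- f1_a - f1_b
  n <- length(d)
  delta <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    t_stat <- if (delta == 0) NA_real_ else Inf * sign(delta)
    p <- if (delta == 0) NA_real_ else if (delta > 0) 0 else 1
    note <- if (delta == 0) "no difference between models" else
      "zero-variance differences; t unbounded"
  } else {
    t_stat <- delta / (s / sqrt(n))
    p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
    note <- NA_character_
  }
  structure(list(delta = delta, t_statistic = t_stat, df = n - 1L,
                 p_value = p, significant = isTRUE(p < alpha),
                 n_pairs = n, alpha = alpha, note = note),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> Delta = %.2f, t(%d) = %s, one-sided p = %s%s\n",
              x$delta, x$df,
              formatC(x$t_statistic, digits = 4, format = "fg"),
              format.pval(x$p_value, digits = 3),
              if (x$significant) " *" else ""))
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}
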