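# Evaluation layer: confusion matrices, per-class metric panels, classifier
# comparisons (chi-squared + phi), subgroup t-tests, variance F-tests,
# Pearson correlations and Bonferroni correction. Metrics whose denominator
# is zero carry an explicit undefined marker (NA, rendered as an en dash),
# never a silent zero.

#' Confusion matrix with predicted rows and true columns
#'
#' @param true_labels,pred_labels Vectors of equal length over
#'   `class_order`.
#' @param class_order Class ordering for rows and columns; defaults to the
#'   four emotions.
#' @return A `qcla_confusion` integer matrix; `counts[p, t]` is the number
#'   of rows predicted `p` whose true class is `t`.
#' @export
confusion <- function(true_labels, pred_labels,
                      class_order = emotion_levels()) {
  if (length(true_labels) != length(pred_labels)) {
    stop_qcla("confusion: length mismatch", "qcla_structural_error")
  }
  tl <- as.character(true_labels)
  pl <- as.character(pred_labels)
  unknown <- setdiff(unique(c(tl, pl)), class_order)
  if (length(unknown) > 0L) {
    stop_qcla(paste0("unknown label(s): ", paste(unknown, collapse = ", ")),
              "qcla_validation_error")
  }
  cm <- table(
    predicted = factor(pl, levels = class_order),
    true = factor(tl, levels = class_order)
  )
  cm <- unclass(cm)
  storage.mode(cm) <- "integer"
  structure(cm, class = c("qcla_confusion", class(cm)))
}

#' Construct a confusion matrix from counts
#'
#' For entering an already-tabulated predicted-by-true matrix (e.g. a
#' published table) into the metric machinery.
#'
#' @param counts Square nonnegative integer matrix, predicted rows by true
#'   columns.
#' @param class_order Labels for rows and columns.
#' @return A `qcla_confusion` matrix.
#' @export
as_confusion <- function(counts, class_order = emotion_levels()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) != length(class_order)) {
    stop_qcla("as_confusion: counts must be square over class_order",
              "qcla_structural_error")
  }
  if (any(counts < 0)) {
    stop_qcla("as_confusion: negative counts", "qcla_validation_error")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(predicted = class_order, true = class_order)
  structure(counts, class = c("qcla_confusion", class(counts)))
}

#' @export
print.qcla_confusion <- function(x, ...) {
  cat("qcla confusion matrix (rows = predicted, columns = true)\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class metric panel from a confusion matrix
#'
#' For each class c with TP = counts[c, c], FP = row total - TP,
#' FN = column total - TP and TN the remainder: sensitivity TP/(TP+FN),
#' precision TP/(TP+FP), specificity TN/(TN+FP), accuracy (TP+TN)/N and
#' F1 = 2PR/(P+R). Any metric with a zero denominator is the undefined
#' marker `NA` (rendered as a dash by [format_metrics()]).
#'
#' @param cm A `qcla_confusion`.
#' @return Data frame with one row per class plus the metric columns;
#'   overall accuracy is attached as `attr(, "overall_accuracy")`.
#' @export
metrics_from_confusion <- function(cm) {
  n <- sum(cm)
  if (n < 1) {
    stop_qcla("metrics_from_confusion: empty matrix", "qcla_validation_error")
  }
  classes <- rownames(cm)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  rows <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[cl, ]) - tp
    fn <- sum(cm[, cl]) - tp
    tn <- n - tp - fp - fn
    precision <- safe_div(tp, tp + fp)
    sensitivity <- safe_div(tp, tp + fn)
    f1 <- if (is.na(precision) || is.na(sensitivity) ||
              precision + sensitivity == 0) {
      NA_real_
    } else {
      2 * precision * sensitivity / (precision + sensitivity)
    }
    data.frame(
      class = cl,
      accuracy = safe_div(tp + tn, n),
      precision = precision,
      specificity = safe_div(tn, tn + fp),
      sensitivity = sensitivity,
      f1 = f1,
      support = tp + fn
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "overall_accuracy") <- overall_accuracy(cm)
  out
}

#' Format a metric panel for display
#'
#' Renders undefined metrics as an en dash.
#'
#' @param metrics Output of [metrics_from_confusion()].
#' @param digits Decimal places.
#' @return Character data frame.
#' @export
format_metrics <- function(metrics, digits = 2) {
  out <- metrics
  for (col in c("accuracy", "precision", "specificity", "sensitivity", "f1")) {
    out[[col]] <- format_metric(metrics[[col]], digits)
  }
  out
}

#' Overall classification accuracy
#'
#' @param cm A `qcla_confusion`.
#' @return Trace over grand total.
#' @export
overall_accuracy <- function(cm) {
  n <- sum(cm)
  if (n < 1) {
    stop_qcla("overall_accuracy: empty matrix", "qcla_validation_error")
  }
  sum(diag(cm)) / n
}

comparison_result <- function(test_name, statistic, df, p_value,
                              effect_size = NA_real_, two_tailed = TRUE) {
  structure(
    list(
      test_name = test_name, statistic = statistic, df = df,
      p_value = p_value, effect_size = effect_size, two_tailed = two_tailed
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  df_txt <- paste(round(unlist(x$df), 2), collapse = ", ")
  cat(sprintf(
    "%s: statistic = %s, df = (%s), p = %s%s\n",
    x$test_name, format_metric(x$statistic, 3), df_txt,
    format_metric(x$p_value, 4),
    if (!is.na(x$effect_size)) {
      sprintf(", effect size = %s", format_metric(x$effect_size, 2))
    } else ""
  ))
  invisible(x)
}

#' Chi-squared comparison of two classification rates
#'
#' Pearson chi-squared (df = 1, no continuity correction) on the 2x2
#' correct/incorrect table of two classifiers, with the phi effect size
#' `sqrt(chi2 / N)`. Reporting conventions differ on which N enters phi, so
#' `n_phi` lets the caller fix it; by default the table total is used.
#'
#' @param correct_a,n_a Correct count and total for classifier A.
#' @param correct_b,n_b Correct count and total for classifier B.
#' @param n_phi N used in the phi denominator (default `n_a + n_b`).
#' @return A `comparison_result` with `statistic`, `df = 1`, `p_value` and
#'   `effect_size` (phi); undefined when a table margin is zero.
#' @export
compare_proportions <- function(correct_a, n_a, correct_b, n_b,
                                n_phi = NULL) {
  if (correct_a > n_a || correct_b > n_b) {
    stop_qcla("compare_proportions: correct count exceeds n",
              "qcla_validation_error")
  }
  tab <- rbind(c(correct_a, n_a - correct_a),
               c(correct_b, n_b - correct_b))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    return(comparison_result("chi-squared (2x2 proportions)",
                             NA_real_, 1L, NA_real_))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (is.null(n_phi)) n_phi <- sum(tab)
  comparison_result(
    "chi-squared (2x2 proportions)",
    statistic = unname(ct$statistic),
    df = 1L,
    p_value = unname(ct$p.value),
    effect_size = sqrt(unname(ct$statistic) / n_phi)
  )
}

#' Phi effect size from a chi-squared statistic
#'
#' `phi = sqrt(chi2 / N)` for a 2x2 table.
#'
#' @param chisq Chi-squared statistic.
#' @param n Sample-size convention for the denominator.
#' @return Phi.
#' @export
phi_from_chisq <- function(chisq, n) {
  if (n <= 0) stop_qcla("phi_from_chisq: n must be positive",
                        "qcla_validation_error")
  sqrt(chisq / n)
}

#' Pooled-variance two-sample t-test
#'
#' Independent-samples t with the pooled variance estimate,
#' df = n1 + n2 - 2.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @param two_tailed Two-tailed p (default) or one-tailed.
#' @return A `comparison_result`; undefined marker when the pooled variance
#'   is zero.
#' @export
two_sample_t <- function(x, y, two_tailed = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_qcla("two_sample_t: each sample needs n >= 2",
              "qcla_validation_error")
  }
  pooled <- ((length(x) - 1) * stats::var(x) +
               (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (pooled < .Machine$double.eps) {
    return(comparison_result("t-test (pooled)", NA_real_,
                             length(x) + length(y) - 2L, NA_real_,
                             two_tailed = two_tailed))
  }
  tt <- t.test(x, y, var.equal = TRUE,
               alternative = if (two_tailed) "two.sided" else "greater")
  comparison_result(
    "t-test (pooled)",
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = unname(tt$p.value),
    two_tailed = two_tailed
  )
}

#' Two-sample variance F-test
#'
#' `F = var(x) / var(y)` with df `(n1 - 1, n2 - 1)`.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @param two_tailed Two-tailed p (default).
#' @return A `comparison_result`; undefined when either variance is zero.
#' @export
variance_f_test <- function(x, y, two_tailed = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_qcla("variance_f_test: each sample needs n >= 2",
              "qcla_validation_error")
  }
  if (stats::var(x) < .Machine$double.eps ||
      stats::var(y) < .Machine$double.eps) {
    return(comparison_result("F-test (variances)", NA_real_,
                             c(length(x) - 1L, length(y) - 1L), NA_real_,
                             two_tailed = two_tailed))
  }
  ft <- var.test(x, y,
                 alternative = if (two_tailed) "two.sided" else "greater")
  comparison_result(
    "F-test (variances)",
    statistic = unname(ft$statistic),
    df = unname(ft$parameter),
    p_value = unname(ft$p.value),
    two_tailed = two_tailed
  )
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y Numeric vectors of equal length, n >= 3, nonzero variances.
#' @return List with `r`, `p`, `n`; undefined markers on zero variance.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_qcla("pearson: need equal-length samples with n >= 3",
              "qcla_validation_error")
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L ||
      stats::var(x) < .Machine$double.eps ||
      stats::var(y) < .Machine$double.eps) {
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value), n = length(x))
}

#' Bonferroni significance flags
#'
#' Flag i is TRUE iff `p[i] <= alpha / m` with m the number of tests.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Familywise alpha (default 0.05).
#' @param m Number of tests; defaults to `length(p_values)`.
#' @return Logical vector of flags (NA p-values give NA flags).
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_qcla("bonferroni: p-values must lie in [0, 1]",
              "qcla_validation_error")
  }
  p_values <= alpha / m
}
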