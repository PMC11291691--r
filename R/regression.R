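# Language-based score estimation: ordinary least squares from the leading
# semantic dimensions to a rating-scale total, with the dimension count
# chosen by grouped inner cross-validation on out-of-fold Pearson r, and
# out-of-fold predicted scores for every row.

ols_coefficients <- function(x, y) {
  xm <- cbind(`(Intercept)` = 1, x)
  fit <- stats::lm.fit(xm, y)
  beta <- fit$coefficients
  if (any(is.na(beta))) {
    qcla_log("rank-deficient design; falling back to a small ridge")
    xtx <- crossprod(xm) + diag(1e-8, ncol(xm))
    beta <- drop(solve(xtx, crossprod(xm, y)))
    names(beta) <- colnames(xm)
  }
  beta
}

ols_predict <- function(beta, x) {
  drop(cbind(1, x[, seq_len(length(beta) - 1L), drop = FALSE]) %*% beta)
}

inner_cv_r <- function(embeddings, totals, groups, d, inner_folds, seed) {
  plan <- make_grouped_folds(groups,
                             n_folds = min(inner_folds,
                                           length(unique(groups))),
                             seed = seed)
  pred <- rep(NA_real_, length(totals))
  for (f in seq_len(plan$n_folds)) {
    test_groups <- names(plan$assignment)[plan$assignment == f]
    is_test <- groups %in% test_groups
    if (!any(is_test) || all(is_test)) next
    beta <- ols_coefficients(embeddings[!is_test, seq_len(d), drop = FALSE],
                             totals[!is_test])
    pred[is_test] <- ols_predict(beta,
                                 embeddings[is_test, , drop = FALSE])
  }
  ok <- !is.na(pred)
  if (sum(ok) < 3L || stats::var(pred[ok]) < .Machine$double.eps ||
      stats::var(totals[ok]) < .Machine$double.eps) {
    return(NA_real_)
  }
  stats::cor(pred[ok], totals[ok])
}

#' Cross-validated language-based predictor of a rating-scale total
#'
#' Outer loop: grouped folds (same construction as the classifier); inside
#' each training fold a grouped inner loop picks the number of leading
#' semantic dimensions maximising out-of-fold Pearson r, an OLS model is
#' fitted on the training rows, and the held-out rows receive out-of-fold
#' predicted scores. A final predictor is fitted on all rows with the
#' dimension count selected on the full data.
#'
#' @param embeddings Response-vector matrix (rows aligned with `totals`).
#' @param totals Numeric rating-scale totals.
#' @param groups Narrative ids for grouped folds.
#' @param scale_name Label stored on the predictor.
#' @param plan Optional outer `cv_plan`; built from `groups` when NULL.
#' @param grid Candidate dimension counts (default [default_dim_grid()]).
#' @param n_folds Outer folds when `plan` is NULL.
#' @param inner_folds Grouped inner folds.
#' @param seed Integer seed.
#' @return A list: `predictor` (a `scale_predictor` with `coefficients` and
#'   `d_selected`), `oof_predictions` (one per row), `oof_r` (Pearson r of
#'   out-of-fold predictions against the totals, NA if undefined),
#'   `fold_d` (dimension count per outer fold).
#' @export
fit_scale_predictor <- function(embeddings, totals, groups,
                                scale_name = "scale", plan = NULL,
                                grid = NULL, n_folds = 10L,
                                inner_folds = 5L, seed = 1L) {
  if (nrow(embeddings) != length(totals)) {
    stop_qcla("fit_scale_predictor: rows misaligned", "qcla_structural_error")
  }
  if (is.null(grid)) grid <- default_dim_grid(ncol(embeddings))
  grid <- sort(unique(pmin(as.integer(grid), ncol(embeddings))))
  if (is.null(plan)) {
    plan <- make_grouped_folds(groups, n_folds = n_folds, seed = seed)
  }
  select_d <- function(rows, seed_f) {
    if (length(grid) == 1L) return(grid)
    rs <- vapply(grid, function(d) {
      inner_cv_r(embeddings[rows, , drop = FALSE], totals[rows],
                 groups[rows], d, inner_folds, seed_f)
    }, numeric(1L))
    if (all(is.na(rs))) return(grid[1L])
    grid[which.max(rs)]
  }
  oof <- rep(NA_real_, length(totals))
  fold_d <- integer(plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    test_groups <- names(plan$assignment)[plan$assignment == f]
    is_test <- groups %in% test_groups
    if (!any(is_test)) next
    train_rows <- which(!is_test)
    d <- select_d(train_rows, child_seed(seed, f))
    fold_d[f] <- d
    beta <- ols_coefficients(
      embeddings[train_rows, seq_len(d), drop = FALSE], totals[train_rows]
    )
    oof[is_test] <- ols_predict(beta, embeddings[is_test, , drop = FALSE])
  }
  d_final <- select_d(seq_along(totals), child_seed(seed, 0L))
  beta_final <- ols_coefficients(
    embeddings[, seq_len(d_final), drop = FALSE], totals
  )
  ok <- !is.na(oof)
  oof_r <- if (sum(ok) >= 3L &&
               stats::var(totals[ok]) > .Machine$double.eps &&
               stats::var(oof[ok]) > .Machine$double.eps) {
    stats::cor(oof[ok], totals[ok])
  } else {
    NA_real_
  }
  predictor <- structure(
    list(scale = scale_name, coefficients = beta_final,
         d_selected = as.integer(d_final)),
    class = "scale_predictor"
  )
  list(predictor = predictor, oof_predictions = oof, oof_r = oof_r,
       fold_d = fold_d)
}

#' @export
print.scale_predictor <- function(x, ...) {
  cat(sprintf("qcla scale predictor for %s: d = %d\n", x$scale, x$d_selected))
  invisible(x)
}

#' Language-based score estimates
#'
#' Evaluates the linear predictor on response embeddings. Estimates are raw
#' linear outputs, deliberately not clipped to the scale range.
#'
#' @param predictor A `scale_predictor`.
#' @param embeddings Response-vector matrix with at least `d_selected`
#'   columns.
#' @return Numeric predicted totals.
#' @export
estimate_scores <- function(predictor, embeddings) {
  if (ncol(embeddings) < predictor$d_selected) {
    stop_qcla("estimate_scores: embedding width below d_selected",
              "qcla_structural_error")
  }
  ols_predict(predictor$coefficients, embeddings)
}

#' Subgroup summary of empirical and estimated scores
#'
#' For one scale: per-group mean and SD of the empirical totals and of the
#' language-based estimates, with pooled two-tailed t-tests on the means
#' and two-tailed F-tests on the variances (uncorrected p-values plus
#' Bonferroni flags over the tests in the summary). A group with fewer than
#' two members yields the summary without tests.
#'
#' @param totals Empirical totals.
#' @param estimates Language-based estimates (same length).
#' @param groups Factor of group labels (e.g. [paq_split()] output).
#' @param alpha Familywise alpha for the Bonferroni flags.
#' @param m Number of tests in the correction family; defaults to the
#'   number of tests computed here (4).
#' @return Data frame with one row per measure (`empirical`, `estimated`):
#'   group means, SDs, ns, t/F statistics and p-values, Bonferroni flags.
#' @export
subgroup_score_summary <- function(totals, estimates, groups,
                                   alpha = 0.05, m = NULL) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  if (length(lv) != 2L) {
    stop_qcla("subgroup_score_summary: exactly two groups expected",
              "qcla_structural_error")
  }
  summarize <- function(values, measure) {
    a <- values[groups == lv[1L]]
    b <- values[groups == lv[2L]]
    testable <- length(a) >= 2L && length(b) >= 2L
    tt <- if (testable) two_sample_t(a, b) else NULL
    ft <- if (testable) variance_f_test(a, b) else NULL
    data.frame(
      measure = measure,
      group_1 = lv[1L], group_2 = lv[2L],
      n_1 = length(a), n_2 = length(b),
      mean_1 = mean(a), mean_2 = mean(b),
      sd_1 = sd(a), sd_2 = sd(b),
      t = if (testable) tt$statistic else NA_real_,
      p_t = if (testable) tt$p_value else NA_real_,
      f = if (testable) ft$statistic else NA_real_,
      p_f = if (testable) ft$p_value else NA_real_
    )
  }
  out <- rbind(summarize(totals, "empirical"),
               summarize(estimates, "estimated"))
  ps <- c(out$p_t, out$p_f)
  if (is.null(m)) m <- sum(!is.na(ps))
  flags <- bonferroni(ps, alpha = alpha, m = max(m, 1L))
  out$sig_t_bonferroni <- flags[seq_len(nrow(out))]
  out$sig_f_bonferroni <- flags[nrow(out) + seq_len(nrow(out))]
  rownames(out) <- NULL
  out
}
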