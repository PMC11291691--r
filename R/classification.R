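# Emotion classification: multinomial logistic regression over semantic
# and/or rating-scale features, evaluated by narrative-grouped 10-fold
# cross-validation with an inner loop that selects how many leading
# semantic dimensions to use.

rs_total_columns <- c("phq9_total", "gad7_total", "swls_total", "hils_total")

#' Assemble a feature set for emotion classification
#'
#' Builds the feature matrix, labels, narrative groups and phase tags for
#' one of the four model families: `"words"` (semantic response vectors),
#' `"rs_totals"` (the four rating-scale totals; PAQ is a moderator, not a
#' feature), `"rs_items"` (the 26 PHQ-9/GAD-7/SWLS/HILS items) or
#' `"words_plus_rs"` (semantic vectors concatenated with the four totals).
#' Records whose words are entirely out of vocabulary are excluded for the
#' semantic kinds.
#'
#' @param records Scored response data frame (see [score_scales()]) with
#'   `condition`, `narrative_id` and `phase` columns.
#' @param kind One of `"words"`, `"rs_totals"`, `"rs_items"`,
#'   `"words_plus_rs"`.
#' @param space A `semantic_space`; required for the semantic kinds.
#' @return A `feature_set` list: `kind`, `semantic` (matrix or NULL),
#'   `scales` (matrix or NULL), `labels` (factor over [emotion_levels()]),
#'   `groups`, `phase`, `row_id` (indices into `records`).
#' @export
feature_set <- function(records,
                        kind = c("words", "rs_totals", "rs_items",
                                 "words_plus_rs"),
                        space = NULL) {
  kind <- match.arg(kind)
  keep <- seq_len(nrow(records))
  semantic <- NULL
  if (kind %in% c("words", "words_plus_rs")) {
    if (is.null(space)) {
      stop_qcla("feature_set: semantic kinds need a space",
                "qcla_structural_error")
    }
    emb <- embed_table(records, space)
    semantic <- emb$matrix
    keep <- emb$kept
  }
  kept <- records[keep, , drop = FALSE]
  scales <- switch(
    kind,
    words = NULL,
    rs_totals = ,
    words_plus_rs = as.matrix(kept[, rs_total_columns, drop = FALSE]),
    rs_items = as.matrix(kept[, unlist(lapply(
      c("PHQ9", "GAD7", "SWLS", "HILS"), scale_item_columns
    )), drop = FALSE])
  )
  labels <- factor(kept$condition, levels = emotion_levels())
  if (any(is.na(labels))) {
    stop_qcla("feature_set: unknown condition label", "qcla_validation_error")
  }
  structure(
    list(
      kind = kind,
      semantic = semantic,
      scales = scales,
      labels = labels,
      groups = as.character(kept$narrative_id),
      phase = as.integer(kept$phase),
      row_id = keep
    ),
    class = "feature_set"
  )
}

n_rows_fs <- function(fs) length(fs$labels)

#' Narrative-grouped cross-validation folds
#'
#' Shuffles the distinct group ids with the given seed and deals them
#' round-robin into folds, so every row tied to one narrative lands in the
#' same fold and fold sizes differ by at most one group.
#'
#' @param groups Character vector of group (narrative) ids, one per row.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the plan is deterministic given it.
#' @return A `cv_plan` list: `n_folds` and `assignment`, a named integer
#'   vector mapping group id to fold.
#' @export
make_grouped_folds <- function(groups, n_folds = 10L, seed = 1L) {
  ids <- unique(as.character(groups))
  if (n_folds < 2L) {
    stop_qcla("make_grouped_folds: n_folds must be >= 2",
              "qcla_validation_error")
  }
  if (length(ids) < n_folds) {
    stop_qcla(
      sprintf("only %d groups for %d folds", length(ids), n_folds),
      "qcla_validation_error"
    )
  }
  shuffled <- with_seed(seed, sample(ids))
  assignment <- setNames(rep_len(seq_len(n_folds), length(ids)), shuffled)
  structure(list(n_folds = n_folds, assignment = assignment),
            class = "cv_plan")
}

#' Default semantic-dimension grid
#'
#' Geometric grid `{2, 3, 5, 8, 12, 18, 27, 40, 60, 90, 135, 200, 300}`
#' clipped to the space dimension, spanning the scales at which short-text
#' LSA classifiers typically peak without an exhaustive search.
#'
#' @param k Space dimension to clip against.
#' @return Integer vector of candidate dimension counts.
#' @export
default_dim_grid <- function(k = 300L) {
  grid <- c(2L, 3L, 5L, 8L, 12L, 18L, 27L, 40L, 60L, 90L, 135L, 200L, 300L)
  out <- grid[grid <= k]
  if (length(out) == 0L) out <- max(1L, k)
  unique(c(out, min(k, max(grid[grid <= k], k))))
}

# Assemble the design matrix: first d semantic dimensions (raw; the SVD is
# already variance-ordered) plus z-scored scale columns.
assemble_design <- function(fs, d, center = NULL, scale = NULL) {
  parts <- list()
  if (!is.null(fs$semantic)) {
    d <- min(d, ncol(fs$semantic))
    parts$sem <- fs$semantic[, seq_len(d), drop = FALSE]
  }
  if (!is.null(fs$scales)) {
    sc <- fs$scales
    if (is.null(center)) {
      center <- colMeans(sc)
      scale <- apply(sc, 2L, sd)
      scale[scale < .Machine$double.eps] <- 1
    }
    parts$sc <- sweep(sweep(sc, 2L, center, "-"), 2L, scale, "/")
  }
  list(x = do.call(cbind, parts), center = center, scale = scale)
}

#' Fit a ridge-penalised multinomial logistic classifier
#'
#' Maximises the L2-penalised multinomial log-likelihood (via
#' [nnet::multinom()] with weight decay) on the first `d` semantic
#' dimensions plus any rating-scale columns. Scale columns are z-scored with
#' the training statistics, which are stored for prediction; semantic
#' dimensions are left raw.
#'
#' @param fs A `feature_set` (optionally row-subset with `rows`).
#' @param d Number of leading semantic dimensions to use (ignored for
#'   scale-only feature sets).
#' @param ridge L2 penalty strength; a small default keeps the optimum
#'   finite on separable data.
#' @param rows Optional integer subset of rows to train on.
#' @return A `qcla_classifier` with `class_order`, `coefficients` (one row
#'   per class, intercept first), `d_selected`, `ridge` and the stored
#'   z-scoring statistics.
#' @export
fit_multinomial <- function(fs, d = NULL, ridge = 1e-4, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(n_rows_fs(fs))
  sub <- fs
  sub$semantic <- if (!is.null(fs$semantic)) {
    fs$semantic[rows, , drop = FALSE]
  }
  sub$scales <- if (!is.null(fs$scales)) fs$scales[rows, , drop = FALSE]
  sub$labels <- fs$labels[rows]
  if (is.null(d)) d <- if (is.null(sub$semantic)) 0L else ncol(sub$semantic)
  present <- levels(droplevels(sub$labels))
  if (length(present) < 2L) {
    stop_qcla("fit_multinomial: need at least two classes",
              "qcla_validation_error")
  }
  if (length(present) < nlevels(sub$labels)) {
    qcla_log("training fold missing class(es): ",
             paste(setdiff(levels(sub$labels), present), collapse = ", "))
  }
  design <- assemble_design(sub, d)
  y <- droplevels(sub$labels)
  df <- data.frame(.y = y, design$x, check.names = FALSE)
  fit <- nnet::multinom(
    .y ~ ., data = df, decay = ridge, trace = FALSE,
    maxit = 2000L, MaxNWts = 100000L
  )
  if (!is.null(fit$convergence) && fit$convergence != 0) {
    stop(errorCondition(
      sprintf("multinomial fit did not converge (value %.4g after maxit)",
              fit$value),
      class = c("qcla_convergence_error", "qcla_error")
    ))
  }
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L)  # two-class case
  # expand to a full class-by-(1+p) matrix; the reference class has zeros
  full <- matrix(0, nrow = length(present), ncol = ncol(design$x) + 1L,
                 dimnames = list(present, c("(Intercept)", colnames(design$x))))
  full[-1L, ] <- cf
  if (any(!is.finite(full))) {
    stop_qcla("fit_multinomial: non-finite coefficients",
              "qcla_convergence_error")
  }
  structure(
    list(
      class_order = levels(fs$labels),
      classes_fit = present,
      coefficients = full,
      d_selected = if (is.null(fs$semantic)) NA_integer_ else as.integer(d),
      ridge = ridge,
      kind = fs$kind,
      scale_center = design$center,
      scale_scale = design$scale
    ),
    class = "qcla_classifier"
  )
}

#' @export
print.qcla_classifier <- function(x, ...) {
  cat(sprintf(
    "qcla multinomial classifier (%s): %d classes, d = %s, ridge = %g\n",
    x$kind, length(x$classes_fit),
    ifelse(is.na(x$d_selected), "-", x$d_selected), x$ridge
  ))
  invisible(x)
}

#' Predict emotion labels and class probabilities
#'
#' Evaluates the stored coefficients by an explicit softmax; the predicted
#' label is the probability argmax, with exact ties broken by the fixed
#' class order.
#'
#' @param classifier A `qcla_classifier`.
#' @param fs A `feature_set` laid out like the training one.
#' @param rows Optional row subset to score.
#' @return List with `labels` (factor over the class order) and `prob`
#'   (rows summing to one; absent-at-training classes get probability 0).
#' @export
predict_classifier <- function(classifier, fs, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(n_rows_fs(fs))
  sub <- fs
  sub$semantic <- if (!is.null(fs$semantic)) {
    fs$semantic[rows, , drop = FALSE]
  }
  sub$scales <- if (!is.null(fs$scales)) fs$scales[rows, , drop = FALSE]
  d <- classifier$d_selected
  if (is.na(d)) d <- 0L
  design <- assemble_design(sub, d,
                            center = classifier$scale_center,
                            scale = classifier$scale_scale)
  p <- ncol(classifier$coefficients) - 1L
  if (ncol(design$x) != p) {
    stop_qcla(
      sprintf("feature width %d does not match training width %d",
              ncol(design$x), p),
      "qcla_structural_error"
    )
  }
  eta <- cbind(1, design$x) %*% t(classifier$coefficients)
  eta <- eta - apply(eta, 1L, max)
  prob_fit <- exp(eta) / rowSums(exp(eta))
  prob <- matrix(0, nrow = nrow(prob_fit),
                 ncol = length(classifier$class_order),
                 dimnames = list(NULL, classifier$class_order))
  prob[, classifier$classes_fit] <- prob_fit
  # argmax with deterministic tie-break by class_order (earlier class wins)
  idx <- apply(prob, 1L, which.max)
  list(
    labels = factor(classifier$class_order[idx],
                    levels = classifier$class_order),
    prob = prob
  )
}

cv_accuracy_over_folds <- function(fs, rows, plan_assignment, d, ridge) {
  correct <- 0L
  total <- 0L
  for (f in sort(unique(plan_assignment))) {
    test_groups <- names(plan_assignment)[plan_assignment == f]
    is_test <- fs$groups[rows] %in% test_groups
    if (!any(is_test) || all(is_test)) next
    # a candidate d whose fit degenerates in an inner fold simply scores NA
    fit <- tryCatch(
      suppressMessages(
        fit_multinomial(fs, d = d, ridge = ridge, rows = rows[!is_test])
      ),
      qcla_validation_error = function(e) NULL,
      qcla_convergence_error = function(e) NULL
    )
    if (is.null(fit)) next
    pred <- predict_classifier(fit, fs, rows = rows[is_test])
    correct <- correct + sum(pred$labels == fs$labels[rows[is_test]])
    total <- total + sum(is_test)
  }
  if (total == 0L) return(NA_real_)
  correct / total
}

#' Select the number of semantic dimensions by inner cross-validation
#'
#' Runs grouped inner cross-validation inside a training fold and returns
#' the grid value with the highest pooled held-out accuracy; ties go to the
#' smallest dimension count.
#'
#' @param fs A `feature_set` with semantic features.
#' @param rows Training-fold row indices.
#' @param grid Candidate dimension counts (clipped to the feature width).
#' @param inner_folds Number of grouped inner folds (default 5).
#' @param seed Seed for the inner fold plan.
#' @param ridge L2 penalty passed to the fits.
#' @return The selected dimension count (integer).
#' @export
select_dimensions <- function(fs, rows = seq_len(n_rows_fs(fs)),
                              grid = default_dim_grid(ncol(fs$semantic)),
                              inner_folds = 5L, seed = 1L, ridge = 1e-4) {
  if (is.null(fs$semantic)) {
    stop_qcla("select_dimensions: feature set has no semantic features",
              "qcla_structural_error")
  }
  grid <- sort(unique(pmin(as.integer(grid), ncol(fs$semantic))))
  if (length(grid) == 0L) {
    stop_qcla("select_dimensions: empty grid", "qcla_validation_error")
  }
  if (length(grid) == 1L) return(grid)
  plan <- make_grouped_folds(fs$groups[rows],
                             n_folds = min(inner_folds,
                                           length(unique(fs$groups[rows]))),
                             seed = seed)
  acc <- vapply(grid, function(d) {
    cv_accuracy_over_folds(fs, rows, plan$assignment, d, ridge)
  }, numeric(1L))
  if (all(is.na(acc))) return(grid[1L])
  grid[which.max(acc)]  # which.max returns the first (smallest d) on ties
}

#' Cross-validated out-of-fold emotion predictions
#'
#' The outer loop holds out one narrative-grouped fold at a time; the model
#' is trained on the remaining folds' rows from the training phases, with
#' the semantic dimension count chosen by a grouped inner loop, and then
#' scores the held-out fold's evaluation-phase rows. Every evaluation row
#' receives exactly one prediction, always from a model never trained on
#' its narrative.
#'
#' @param fs A `feature_set`.
#' @param plan Optional `cv_plan`; built from `fs$groups` when NULL.
#' @param grid Candidate semantic dimension counts.
#' @param ridge L2 penalty.
#' @param seed Seed for fold construction (outer and inner).
#' @param n_folds Outer folds when `plan` is NULL (default 10).
#' @param inner_folds Grouped inner folds for dimension selection.
#' @param train_phases Phases pooled for training (default both).
#' @param eval_phase Phase scored out of fold (default 2); NULL scores all.
#' @return A data frame (`qcla_cv_predictions`): `row_id` (index into the
#'   feature set), `fold`, `true`, `pred`, `d_selected` and one probability
#'   column per class.
#' @export
cross_validated_predictions <- function(fs, plan = NULL,
                                        grid = NULL,
                                        ridge = 1e-4, seed = 1L,
                                        n_folds = 10L, inner_folds = 5L,
                                        train_phases = c(1L, 2L),
                                        eval_phase = 2L) {
  if (is.null(plan)) {
    plan <- make_grouped_folds(fs$groups, n_folds = n_folds, seed = seed)
  }
  if (is.null(grid)) {
    grid <- if (is.null(fs$semantic)) integer(0) else {
      default_dim_grid(ncol(fs$semantic))
    }
  }
  out <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    test_groups <- names(plan$assignment)[plan$assignment == f]
    in_fold <- fs$groups %in% test_groups
    train_rows <- which(!in_fold & fs$phase %in% train_phases)
    eval_rows <- if (is.null(eval_phase)) {
      which(in_fold)
    } else {
      which(in_fold & fs$phase %in% eval_phase)
    }
    if (length(eval_rows) == 0L) next
    d <- if (!is.null(fs$semantic)) {
      select_dimensions(fs, rows = train_rows, grid = grid,
                        inner_folds = inner_folds,
                        seed = child_seed(seed, f), ridge = ridge)
    } else {
      NA_integer_
    }
    fit <- fit_multinomial(fs, d = d, ridge = ridge, rows = train_rows)
    pred <- predict_classifier(fit, fs, rows = eval_rows)
    out[[f]] <- data.frame(
      row_id = eval_rows,
      fold = f,
      true = fs$labels[eval_rows],
      pred = pred$labels,
      d_selected = if (is.na(d)) NA_integer_ else as.integer(d),
      pred$prob,
      check.names = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$row_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("qcla_cv_predictions", "data.frame")
  res
}
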