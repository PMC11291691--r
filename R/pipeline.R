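# End-to-end orchestration: simulate (or load) -> build space -> embed ->
# classify under grouped nested CV -> evaluation statistics -> scale
# prediction -> word clouds, gathered into one report bundle.

accuracy_split <- function(correct, grp) {
  lv <- levels(grp)
  a <- correct[grp == lv[1L]]
  b <- correct[grp == lv[2L]]
  tt <- if (length(a) >= 2L && length(b) >= 2L) two_sample_t(a, b) else NULL
  list(
    acc_low = if (length(a)) mean(a) else NA_real_,
    acc_high = if (length(b)) mean(b) else NA_real_,
    p = if (is.null(tt)) NA_real_ else tt$p_value,
    t = if (is.null(tt)) NA_real_ else tt$statistic
  )
}

#' Run the full assessment pipeline
#'
#' Simulates (or accepts) a two-phase study, builds the LSA space from the
#' corpus, runs grouped nested-CV multinomial classification for each
#' requested feature family, computes the evaluation statistics (confusion
#' matrices, metric panels, chi-squared model comparisons with phi,
#' alexithymia subgroup accuracies with t-tests), fits cross-validated
#' language-based predictors of the four rating scales (out-of-fold and
#' test-retest correlations, subgroup mean/SD panels with t/F tests and
#' Bonferroni flags), and emits ranked word clouds. Deterministic for a
#' fixed seed.
#'
#' @param cfg A [synthetic_config()] used when `records`/`corp` are NULL.
#' @param records Optional scored response table (see [score_scales()]).
#' @param corp Optional `qcla_corpus`; required when `records` is given.
#' @param k Semantic space dimension (default 300, clamped to rank).
#' @param feature_kinds Model families to run.
#' @param n_folds,inner_folds Outer/inner grouped fold counts.
#' @param grid Semantic-dimension grid (default [default_dim_grid()]).
#' @param ridge L2 penalty for the classifier fits.
#' @param paq_threshold_mode `"fixed"` uses `paq_threshold`; `"median"`
#'   recomputes the split point from the sample via [median_threshold()].
#' @param paq_threshold Fixed alexithymia split point (default 68).
#' @param cloud_k Entries per word cloud.
#' @param with_wordclouds Set FALSE to skip the word-cloud stage.
#' @param seed Master seed for folds and simulation.
#' @return A `qcla_report` list; see the package vignette for the layout.
#' @export
run_pipeline <- function(cfg = synthetic_config(seed = seed),
                         records = NULL, corp = NULL,
                         k = 300L,
                         feature_kinds = c("words", "rs_totals", "rs_items",
                                           "words_plus_rs"),
                         n_folds = 10L, inner_folds = 5L,
                         grid = NULL, ridge = 1e-4,
                         paq_threshold_mode = c("fixed", "median"),
                         paq_threshold = 68L,
                         cloud_k = 25L,
                         with_wordclouds = TRUE,
                         seed = 1L) {
  paq_threshold_mode <- match.arg(paq_threshold_mode)
  if (is.null(records)) {
    sim <- simulate_study(cfg)
    records <- sim$records
    corp <- sim$corpus
  } else if (is.null(corp)) {
    stop_qcla("run_pipeline: records supplied without a corpus",
              "qcla_structural_error")
  }
  space <- suppressMessages(train_space(corp, k = k))
  if (paq_threshold_mode == "median") {
    paq_threshold <- median_threshold(records$paq_total)
  }

  # -- classification stage, one model family at a time ---------------------
  acc_rows <- list()
  confusions <- list()
  panels <- list()
  cvps <- list()
  mean_d <- list()
  for (kind in feature_kinds) {
    fs <- suppressMessages(feature_set(records, kind, space))
    cvp <- suppressMessages(cross_validated_predictions(
      fs, grid = grid, ridge = ridge, seed = seed,
      n_folds = n_folds, inner_folds = inner_folds
    ))
    cvps[[kind]] <- cvp
    cm <- confusion(cvp$true, cvp$pred)
    confusions[[kind]] <- cm
    panels[[kind]] <- metrics_from_confusion(cm)
    correct <- as.integer(cvp$pred == cvp$true)
    eval_rec <- records[fs$row_id[cvp$row_id], , drop = FALSE]
    narr <- if ("narrator_paq" %in% names(eval_rec)) {
      accuracy_split(correct,
                     paq_split(eval_rec$narrator_paq, paq_threshold))
    } else {
      list(acc_low = NA_real_, acc_high = NA_real_, p = NA_real_)
    }
    evalr <- accuracy_split(correct,
                            paq_split(eval_rec$paq_total, paq_threshold))
    acc_rows[[kind]] <- data.frame(
      kind = kind,
      accuracy = overall_accuracy(cm),
      n_eval = sum(cm),
      narrator_low = narr$acc_low, narrator_high = narr$acc_high,
      p_narrator = narr$p,
      evaluator_low = evalr$acc_low, evaluator_high = evalr$acc_high,
      p_evaluator = evalr$p
    )
    mean_d[[kind]] <- if (all(is.na(cvp$d_selected))) NA_real_ else {
      mean(unique(cvp[, c("fold", "d_selected")])$d_selected)
    }
  }
  accuracy <- do.call(rbind, acc_rows)
  rownames(accuracy) <- NULL

  # -- pairwise model comparisons (chi-squared + phi) -----------------------
  n_correct <- function(kind) {
    sum(cvps[[kind]]$pred == cvps[[kind]]$true)
  }
  n_eval <- function(kind) nrow(cvps[[kind]])
  comparisons <- list()
  pairs <- list(c("words", "rs_totals"), c("rs_items", "rs_totals"),
                c("words", "words_plus_rs"))
  for (p in pairs) {
    if (all(p %in% feature_kinds)) {
      comparisons[[paste(p, collapse = "_vs_")]] <-
        compare_proportions(n_correct(p[1L]), n_eval(p[1L]),
                            n_correct(p[2L]), n_eval(p[2L]))
    }
  }

  # -- language-based rating-scale estimation -------------------------------
  fs_words <- suppressMessages(feature_set(records, "words", space))
  emb <- fs_words$semantic
  kept <- records[fs_words$row_id, , drop = FALSE]
  scale_rows <- list()
  subgroups <- list()
  estimates <- list()
  for (s in c("PHQ9", "GAD7", "SWLS", "HILS")) {
    total_col <- paste0(tolower(s), "_total")
    res <- suppressMessages(fit_scale_predictor(
      emb, kept[[total_col]], fs_words$groups, scale_name = s,
      grid = grid, n_folds = n_folds, inner_folds = inner_folds,
      seed = seed
    ))
    estimates[[s]] <- res$oof_predictions
    pr <- pearson(res$oof_predictions, kept[[total_col]])
    # test-retest: each Phase-2 row paired with its narrative's Phase-1 value
    p1 <- kept[kept$phase == 1L, , drop = FALSE]
    p2 <- kept[kept$phase == 2L, , drop = FALSE]
    m1 <- match(p2$narrative_id, p1$narrative_id)
    ok <- !is.na(m1)
    retest_rs <- pearson(p1[[total_col]][m1[ok]], p2[[total_col]][ok])
    est1 <- res$oof_predictions[kept$phase == 1L]
    est2 <- res$oof_predictions[kept$phase == 2L]
    retest_w <- pearson(est1[m1[ok]], est2[ok])
    scale_rows[[s]] <- data.frame(
      scale = s, d_selected = res$predictor$d_selected,
      r_pred = pr$r, p_pred = pr$p,
      retest_r_rs = retest_rs$r, retest_p_rs = retest_rs$p,
      retest_r_words = retest_w$r, retest_p_words = retest_w$p
    )
    subgroups[[s]] <- subgroup_score_summary(
      kept[[total_col]], res$oof_predictions,
      paq_split(kept$paq_total, paq_threshold)
    )
  }
  scales_table <- do.call(rbind, scale_rows)
  rownames(scales_table) <- NULL

  # -- word clouds ----------------------------------------------------------
  wordclouds <- NULL
  if (with_wordclouds) {
    d_cloud <- suppressMessages(select_dimensions(
      fs_words, grid = if (is.null(grid)) {
        default_dim_grid(ncol(emb))
      } else {
        grid
      },
      inner_folds = inner_folds, seed = child_seed(seed, 201L),
      ridge = ridge
    ))
    clf_all <- suppressMessages(
      fit_multinomial(fs_words, d = d_cloud, ridge = ridge)
    )
    wordclouds <- list(
      emotions = emotion_word_clouds(space, clf_all, k = cloud_k),
      cells = suppressWarnings(suppressMessages(
        paq_phq_cells(kept, space, d = d_cloud,
                      paq_threshold = paq_threshold, k = cloud_k,
                      ridge = ridge)
      )),
      d_used = d_cloud
    )
  }

  structure(
    list(
      space = list(n_words = length(space$vocabulary), k = space$k),
      n_records = nrow(records),
      paq_threshold = paq_threshold,
      baseline_accuracy = 1 / length(emotion_levels()),
      accuracy = accuracy,
      confusions = confusions,
      metric_panels = panels,
      comparisons = comparisons,
      mean_d_selected = mean_d,
      scales = scales_table,
      subgroups = subgroups,
      estimates = estimates,
      wordclouds = wordclouds,
      cv_predictions = cvps,
      seed = seed
    ),
    class = "qcla_report"
  )
}

#' @export
print.qcla_report <- function(x, ...) {
  cat("qcla pipeline report\n")
  cat(sprintf("  space: %d words x %d dims; %d records; chance = %.2f\n",
              x$space$n_words, x$space$k, x$n_records, x$baseline_accuracy))
  cat("  classification accuracy (Phase-2, out of fold):\n")
  for (i in seq_len(nrow(x$accuracy))) {
    cat(sprintf("    %-13s %.3f\n",
                x$accuracy$kind[i], x$accuracy$accuracy[i]))
  }
  cat("  scale prediction (out-of-fold Pearson r):\n")
  for (i in seq_len(nrow(x$scales))) {
    cat(sprintf("    %-5s r = %s\n", x$scales$scale[i],
                format_metric(x$scales$r_pred[i], 2)))
  }
  invisible(x)
}

report_json_payload <- function(report) {
  list(
    space = report$space,
    n_records = report$n_records,
    paq_threshold = report$paq_threshold,
    baseline_accuracy = report$baseline_accuracy,
    accuracy = report$accuracy,
    confusions = lapply(report$confusions, function(cm) {
      as.data.frame(unclass(cm))
    }),
    metric_panels = report$metric_panels,
    comparisons = lapply(report$comparisons, unclass),
    mean_d_selected = report$mean_d_selected,
    scales = report$scales,
    subgroups = report$subgroups,
    wordclouds = if (!is.null(report$wordclouds)) {
      list(emotions = report$wordclouds$emotions,
           cells = report$wordclouds$cells,
           d_used = report$wordclouds$d_used)
    },
    seed = report$seed
  )
}

md_table <- function(df, digits = 3) {
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "–", round(v, digits)) else v
  }
  df[] <- lapply(df, fmt)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) {
    paste0("| ", paste(r, collapse = " | "), " |")
  })
  c(header, sep, rows)
}

#' Write a pipeline report bundle
#'
#' Emits `report.json` (the full machine-readable bundle) and `report.md`
#' (accuracy table, confusion matrices, metric panels, comparisons, scale
#' correlations and subgroup panels) into a directory.
#'
#' @param report A `qcla_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_json_payload(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  lines <- c(
    "# QCLA pipeline report", "",
    sprintf("Semantic space: %d words, %d dimensions. Records: %d. Seed: %d.",
            report$space$n_words, report$space$k, report$n_records,
            report$seed),
    sprintf("Chance baseline for four balanced classes: %.2f.",
            report$baseline_accuracy),
    "", "## Classification accuracy (out-of-fold, Phase 2)", "",
    md_table(report$accuracy), ""
  )
  for (kind in names(report$confusions)) {
    cm <- as.data.frame(unclass(report$confusions[[kind]]))
    cm <- cbind(predicted = rownames(cm), cm)
    lines <- c(lines,
               sprintf("## Confusion matrix: %s (rows predicted, columns true)",
                       kind),
               "", md_table(cm), "",
               sprintf("## Metric panel: %s", kind), "",
               md_table(format_metrics(report$metric_panels[[kind]])), "")
  }
  if (length(report$comparisons)) {
    comp <- do.call(rbind, lapply(names(report$comparisons), function(nm) {
      cr <- report$comparisons[[nm]]
      data.frame(comparison = nm, chisq = cr$statistic, df = 1,
                 p = cr$p_value, phi = cr$effect_size)
    }))
    lines <- c(lines, "## Model comparisons (chi-squared, phi)", "",
               md_table(comp), "")
  }
  lines <- c(lines, "## Rating-scale prediction and test-retest", "",
             md_table(report$scales), "")
  for (s in names(report$subgroups)) {
    lines <- c(lines, sprintf("## Alexithymia subgroups: %s", s), "",
               md_table(report$subgroups[[s]]), "")
  }
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
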