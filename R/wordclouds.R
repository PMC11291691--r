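# Ranked word tables ("word clouds"): every vocabulary word, embedded as
# its own unit vector, is scored by a trained model; the top-coefficient
# words per target are reported with corpus frequencies and a
# permutation-null Bonferroni significance screen. Output is tabular; no
# graphics.

#' Score every vocabulary word with a trained model
#'
#' Each word's own unit vector is pushed through the model: for a
#' multinomial classifier the score is the class logit (linear predictor
#' restricted to the semantic dimensions the model used); for a scale
#' predictor it is the predicted scale value.
#'
#' @param space A `semantic_space`.
#' @param model A `qcla_classifier` or `scale_predictor`.
#' @return Numeric matrix, one row per vocabulary word, one column per
#'   target (classes, or the single scale).
#' @export
word_coefficients <- function(space, model) {
  v <- space$vectors
  if (inherits(model, "qcla_classifier")) {
    cf <- model$coefficients
    dim_cols <- grep("^dim", colnames(cf), value = TRUE)
    if (length(dim_cols) == 0L) {
      stop_qcla("word_coefficients: classifier has no semantic coefficients",
                "qcla_structural_error")
    }
    scores <- sweep(
      v[, dim_cols, drop = FALSE] %*% t(cf[, dim_cols, drop = FALSE]),
      2L, cf[, "(Intercept)"], "+"
    )
    full <- matrix(NA_real_, nrow = nrow(v), ncol = length(model$class_order),
                   dimnames = list(space$vocabulary, model$class_order))
    full[, model$classes_fit] <- scores
    full
  } else if (inherits(model, "scale_predictor")) {
    matrix(estimate_scores(model, v), ncol = 1L,
           dimnames = list(space$vocabulary, model$scale))
  } else {
    stop_qcla("word_coefficients: unsupported model type",
              "qcla_structural_error")
  }
}

#' Top-k word-cloud entries
#'
#' The k highest-coefficient words, ties broken by higher corpus frequency
#' and then lexicographically; invariant to input order.
#'
#' @param words Character vector of words.
#' @param coefficients Scores aligned with `words`.
#' @param frequency Corpus occurrence counts aligned with `words`.
#' @param k Number of entries (default 25, the conventional cloud size).
#' @param p_raw Optional per-word p-values to carry through.
#' @param significant Optional per-word significance flags.
#' @return Data frame of `word_cloud_entry` rows: `rank`, `word`,
#'   `coefficient`, `frequency` and, when supplied, `p_raw` /
#'   `significant_bonferroni`.
#' @export
top_k <- function(words, coefficients, frequency, k = 25L,
                  p_raw = NULL, significant = NULL) {
  if (k < 1L) {
    stop_qcla("top_k: k must be >= 1", "qcla_validation_error")
  }
  if (k > length(words)) {
    warning(sprintf("top_k: k = %d exceeds vocabulary size %d; returning all",
                    k, length(words)))
    k <- length(words)
  }
  ord <- order(-coefficients, -frequency, words)
  idx <- ord[seq_len(k)]
  out <- data.frame(
    rank = seq_len(k),
    word = words[idx],
    coefficient = coefficients[idx],
    frequency = frequency[idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(p_raw)) out$p_raw <- p_raw[idx]
  if (!is.null(significant)) out$significant_bonferroni <- significant[idx]
  rownames(out) <- NULL
  out
}

fit_for_screen <- function(embeddings, y, type, d, ridge) {
  if (type == "class") {
    fs <- structure(
      list(kind = "words", semantic = embeddings, scales = NULL,
           labels = y, groups = as.character(seq_along(y)),
           phase = rep(1L, length(y)), row_id = seq_along(y)),
      class = "feature_set"
    )
    suppressMessages(fit_multinomial(fs, d = d, ridge = ridge))
  } else {
    structure(
      list(scale = "scale",
           coefficients = ols_coefficients(
             embeddings[, seq_len(d), drop = FALSE], y
           ),
           d_selected = as.integer(d)),
      class = "scale_predictor"
    )
  }
}

#' Permutation significance screen for word scores
#'
#' Builds a label-permutation null for each word's model score: the model
#' is refitted on permuted labels (or targets) with the same dimension
#' count, the per-word scores are recomputed, and each word's p-value is
#' the permutation fraction with a score at least as large as observed
#' (with the +1 correction). Flags are Bonferroni-corrected across the
#' vocabulary.
#'
#' @param space A `semantic_space`.
#' @param embeddings Response embedding matrix used to fit the model.
#' @param y Emotion labels (factor) for `type = "class"` or numeric totals
#'   for `type = "scale"`.
#' @param type `"class"` or `"scale"`.
#' @param target For `"class"`, the class whose scores are screened.
#' @param d Number of leading semantic dimensions for the fits.
#' @param n_perm Number of permutations (at least 100; default 1000).
#' @param alpha Familywise alpha for the Bonferroni flags.
#' @param ridge L2 penalty for the classifier fits.
#' @param seed Integer seed for the permutation stream.
#' @return List with `p_raw` (named per-word p-values), `significant`
#'   (Bonferroni flags), `observed` (the word scores) and `n_perm`.
#' @export
significance_screen <- function(space, embeddings, y,
                                type = c("class", "scale"),
                                target = NULL, d = 10L, n_perm = 1000L,
                                alpha = 0.05, ridge = 1e-4, seed = 1L) {
  type <- match.arg(type)
  if (n_perm < 100L) {
    stop_qcla("significance_screen: configure at least 100 permutations",
              "qcla_validation_error")
  }
  m <- length(space$vocabulary)
  floor_p <- 1 / (n_perm + 1)
  if (floor_p > alpha / m) {
    warning(sprintf(
      paste0("significance_screen: %d permutations give a p-value floor of ",
             "%.2g, above the Bonferroni threshold %.2g; no word can be ",
             "flagged"),
      n_perm, floor_p, alpha / m
    ))
  }
  d <- min(d, ncol(embeddings))
  score_of <- function(model) {
    sc <- word_coefficients(space, model)
    if (type == "class") {
      if (is.null(target)) {
        stop_qcla("significance_screen: target class required",
                  "qcla_structural_error")
      }
      sc[, target]
    } else {
      sc[, 1L]
    }
  }
  observed <- score_of(fit_for_screen(embeddings, y, type, d, ridge))
  exceed <- integer(m)
  with_seed(child_seed(seed, 7L), {
    for (b in seq_len(n_perm)) {
      y_perm <- sample(y)
      perm_scores <- score_of(fit_for_screen(embeddings, y_perm, type, d,
                                             ridge))
      exceed <- exceed + (perm_scores >= observed)
    }
  })
  p_raw <- setNames((exceed + 1) / (n_perm + 1), space$vocabulary)
  list(
    p_raw = p_raw,
    significant = bonferroni(p_raw, alpha = alpha, m = m),
    observed = observed,
    n_perm = n_perm
  )
}

#' Emotion word clouds from a trained classifier
#'
#' One ranked word table per emotion class.
#'
#' @param space A `semantic_space` (with `word_frequency`, e.g. from
#'   [train_space()]).
#' @param classifier A `qcla_classifier` trained on semantic features.
#' @param k Entries per cloud (default 25).
#' @return Named list of data frames, one per class.
#' @export
emotion_word_clouds <- function(space, classifier, k = 25L) {
  scores <- word_coefficients(space, classifier)
  freq <- word_cloud_frequency(space)
  lapply(setNames(nm = classifier$classes_fit), function(cl) {
    top_k(space$vocabulary, scores[, cl], freq, k = k)
  })
}

word_cloud_frequency <- function(space) {
  if (!is.null(space$word_frequency)) {
    as.integer(space$word_frequency[space$vocabulary])
  } else {
    rep(1L, length(space$vocabulary))
  }
}

#' Word clouds for alexithymia-by-depression cells
#'
#' Splits records into four cells by narrator alexithymia (PAQ at the given
#' threshold) and depression score (PHQ-9 at the sample median), then for
#' each cell fits a ridge-stabilised cell-vs-rest logistic model on the
#' response embeddings and scores every vocabulary word by its cell logit.
#'
#' @param records Scored response records (with `paq_total`, `phq9_total`).
#' @param space A `semantic_space`.
#' @param d Leading dimensions for the cell models.
#' @param paq_threshold PAQ split point (default 68).
#' @param k Entries per cloud.
#' @param ridge L2 penalty for the cell fits.
#' @return Named list of four data frames (`lowPAQ_lowPHQ`, `lowPAQ_highPHQ`,
#'   `highPAQ_lowPHQ`, `highPAQ_highPHQ`); an empty cell yields an empty
#'   cloud with a warning.
#' @export
paq_phq_cells <- function(records, space, d = 10L, paq_threshold = 68L,
                          k = 25L, ridge = 1e-4) {
  emb <- embed_table(records, space)
  kept <- records[emb$kept, , drop = FALSE]
  paq_grp <- paq_split(kept$paq_total, threshold = paq_threshold)
  phq_thr <- median_threshold(kept$phq9_total)
  phq_grp <- factor(ifelse(kept$phq9_total <= phq_thr, "low", "high"),
                    levels = c("low", "high"))
  freq <- word_cloud_frequency(space)
  d <- min(d, ncol(emb$matrix))
  cells <- list(
    lowPAQ_lowPHQ = paq_grp == "low" & phq_grp == "low",
    lowPAQ_highPHQ = paq_grp == "low" & phq_grp == "high",
    highPAQ_lowPHQ = paq_grp == "high" & phq_grp == "low",
    highPAQ_highPHQ = paq_grp == "high" & phq_grp == "high"
  )
  lapply(setNames(nm = names(cells)), function(cell) {
    member <- cells[[cell]]
    if (!any(member) || all(member)) {
      warning(sprintf("paq_phq_cells: cell %s is degenerate (n = %d)",
                      cell, sum(member)))
      return(data.frame(rank = integer(0), word = character(0),
                        coefficient = numeric(0), frequency = integer(0)))
    }
    y <- factor(ifelse(member, "cell", "other"),
                levels = c("other", "cell"))
    fit <- fit_for_screen(emb$matrix, y, "class", d, ridge)
    scores <- word_coefficients(space, fit)[, "cell"]
    top_k(space$vocabulary, scores, freq, k = min(k, length(scores)))
  })
}
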