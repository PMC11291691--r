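# Shared fixtures: small synthetic configurations, a tiny deterministic
# semantic space, and the published Phase-2 confusion matrices used as
# frozen worked examples.

small_config <- function(seed = 1, ...) {
  synthetic_config(
    n_phase1 = 40L, n_phase2 = 80L,
    vocab_per_emotion = 40L,
    corpus_responses = 400L,
    seed = seed,
    ...
  )
}

small_study <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      sim <- simulate_study(small_config(seed = seed))
      sim$space <- suppressMessages(train_space(sim$corpus, k = 60L))
      cache[[key]] <- sim
    }
    cache[[key]]
  }
})

# A hand-checkable space: three words with known orthogonal unit vectors.
toy_space <- function() {
  vectors <- rbind(
    alpha = c(1, 0, 0),
    beta  = c(0, 1, 0),
    gamma = c(0, 0, 1)
  )
  colnames(vectors) <- paste0("dim", 1:3)
  structure(
    list(vocabulary = rownames(vectors), vectors = vectors,
         singular_values = c(3, 2, 1), k = 3L, weighting = "us"),
    class = "semantic_space"
  )
}

# Published Phase-2 confusion matrices (predicted rows, true columns;
# class order harmony, satisfaction, depression, anxiety). Used as frozen
# worked examples for the metric layer.
semantic_confusion_reference <- function() {
  as_confusion(rbind(
    c(29, 16, 4, 0),
    c(6, 31, 1, 3),
    c(6, 20, 42, 14),
    c(2, 7, 9, 42)
  ))
}

rating_scale_confusion_reference <- function() {
  as_confusion(rbind(
    c(10, 28, 2, 0),
    c(22, 15, 1, 15),
    c(11, 31, 51, 44),
    c(0, 0, 2, 0)
  ))
}

# Feature set with a planted signal: classes separated in the first
# n_signal dimensions, pure noise beyond; groups of `group_size` rows.
planted_feature_set <- function(n_per_class = 30L, n_dims = 30L,
                                n_signal = 5L, sep = 3, noise = 1,
                                group_size = 2L, seed = 42L) {
  classes <- emotion_levels()
  n_signal <- min(n_signal, n_dims)
  set.seed(seed)
  n <- n_per_class * length(classes)
  labels <- factor(rep(classes, each = n_per_class), levels = classes)
  centers <- matrix(0, length(classes), n_signal)
  for (i in seq_along(classes)) {
    centers[i, ((i - 1L) %% n_signal) + 1L] <- sep
    centers[i, (i %% n_signal) + 1L] <- -sep / 2
  }
  x <- matrix(rnorm(n * n_dims, sd = noise), n, n_dims)
  x[, seq_len(n_signal)] <- x[, seq_len(n_signal)] +
    centers[as.integer(labels), , drop = FALSE]
  colnames(x) <- paste0("dim", seq_len(n_dims))
  structure(
    list(kind = "words", semantic = x, scales = NULL, labels = labels,
         groups = as.character((seq_len(n) - 1L) %/% group_size),
         phase = rep(2L, n), row_id = seq_len(n)),
    class = "feature_set"
  )
}
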