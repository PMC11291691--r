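test_that("word scores equal manual model evaluation per word", {
  fs <- planted_feature_set(n_per_class = 20, n_dims = 3, n_signal = 3,
                            sep = 2, seed = 5)
  fit <- fit_multinomial(fs, d = 3)
  space <- toy_space()
  scores <- word_coefficients(space, fit)
  cf <- fit$coefficients
  for (w in space$vocabulary) {
    manual <- cf[, 1] + drop(cf[, -1] %*% space$vectors[w, ])
    expect_equal(unname(scores[w, fit$classes_fit]), unname(manual),
                 tolerance = 1e-12)
  }
  # a word aligned with a class's coefficient direction scores highest there
  cl <- "depression"
  direction <- cf[cl, -1] / sqrt(sum(cf[cl, -1]^2))
  aligned_space <- toy_space()
  aligned_space$vectors["alpha", ] <- direction
  s2 <- word_coefficients(aligned_space, fit)
  expect_equal(which.max(s2[, cl]), c(alpha = 1L))
})

test_that("scale-predictor word scores are the predicted scale values", {
  set.seed(3)
  emb <- matrix(rnorm(60 * 3), 60, 3)
  y <- 10 + 2 * emb[, 1] + rnorm(60, sd = 0.1)
  res <- suppressMessages(fit_scale_predictor(
    emb, y, as.character(1:60), grid = 3, n_folds = 4, inner_folds = 3,
    seed = 1, scale_name = "PHQ9"
  ))
  space <- toy_space()
  sc <- word_coefficients(space, res$predictor)
  expect_equal(colnames(sc), "PHQ9")
  expect_equal(unname(sc[, 1]),
               unname(estimate_scores(res$predictor, space$vectors)))
})

test_that("top_k returns the sorted prefix with documented tie-breaks", {
  words <- c("d", "b", "a", "c", "e")
  coefs <- c(1, 3, 3, 2, 0.5)
  freq <- c(9, 2, 7, 1, 1)
  out <- top_k(words, coefs, freq, k = 3)
  # ties on coefficient 3: higher frequency ("a", 7) precedes "b"
  expect_equal(out$word, c("a", "b", "c"))
  expect_equal(out$rank, 1:3)
  expect_equal(top_k(words, coefs, freq, k = 1)$word, "a")
  # order invariance
  perm <- sample(5)
  out2 <- top_k(words[perm], coefs[perm], freq[perm], k = 3)
  expect_equal(out2, out)
  # full-sort prefix oracle on random input
  set.seed(8)
  w <- paste0("w", 1:40)
  co <- rnorm(40)
  fr <- sample(1:50, 40, replace = TRUE)
  got <- top_k(w, co, fr, k = 10)
  oracle <- w[order(-co, -fr, w)][1:10]
  expect_equal(got$word, oracle)
  expect_warning(big <- top_k(words, coefs, freq, k = 10), "exceeds")
  expect_equal(nrow(big), 5)
  expect_error(top_k(words, coefs, freq, k = 0),
               class = "qcla_validation_error")
})

test_that("a word exclusive to one emotion tops that emotion's cloud", {
  cfg <- small_config(seed = 6, word_noise_low = 0.1, word_noise_high = 0.1)
  sim <- simulate_study(cfg)
  space <- suppressMessages(train_space(sim$corpus, k = 40))
  fs <- suppressMessages(feature_set(sim$records, "words", space))
  fit <- suppressMessages(fit_multinomial(fs, d = 20))
  clouds <- emotion_word_clouds(space, fit, k = 25)
  # depression-vocabulary words should dominate the depression cloud
  dep_cloud <- clouds$depression$word
  expect_gt(mean(startsWith(dep_cloud, "dep_")), 0.6)
  # the most frequent depression-exclusive word ranks in that cloud
  dep_vocab <- grep("^dep_", sim$corpus$vocabulary, value = TRUE)
  top_dep <- dep_vocab[which.max(sim$corpus$word_frequency[dep_vocab])]
  expect_true(top_dep %in% dep_cloud)
  # and depression words are far rarer in the harmony cloud
  har_cloud <- clouds$harmony$word
  expect_lt(mean(startsWith(har_cloud, "dep_")),
            mean(startsWith(dep_cloud, "dep_")) - 0.3)
})

test_that("permutation screen flags a planted word and respects Bonferroni", {
  # tiny vocabulary so the Bonferroni floor is reachable with few permutations
  set.seed(44)
  vocab <- c("gloom", paste0("filler", 1:9))
  vectors <- diag(10)[, 1:6]
  rownames(vectors) <- vocab
  colnames(vectors) <- paste0("dim", 1:6)
  space <- structure(
    list(vocabulary = vocab, vectors = vectors,
         singular_values = rep(1, 6), k = 6L, weighting = "us"),
    class = "semantic_space"
  )
  n <- 80
  words <- replicate(n, sample(vocab[-1], 4), simplify = FALSE)
  y <- rnorm(n, 10, 2)
  high <- order(y, decreasing = TRUE)[1:30]
  words[high] <- lapply(words[high], function(w) c("gloom", w[1:3]))
  emb <- suppressMessages(embed_table(words, space))$matrix
  scr <- significance_screen(space, emb, y, type = "scale", d = 6,
                             n_perm = 400, seed = 2)
  expect_true(scr$significant[["gloom"]])
  expect_equal(sum(scr$significant), 1)
  # flags are always a subset of uncorrected flags
  expect_true(all(!scr$significant | (scr$p_raw <= 0.05)))
  expect_error(
    significance_screen(space, emb, y, type = "scale", d = 6, n_perm = 50),
    class = "qcla_validation_error"
  )
  expect_warning(
    significance_screen(space, emb[1:20, ], y[1:20], type = "scale",
                        d = 6, n_perm = 100, seed = 1),
    "floor"
  )
})

test_that("permutation p-values are well calibrated under the null", {
  set.seed(21)
  vocab <- paste0("w", 1:8)
  vectors <- diag(8)[, 1:5]
  rownames(vectors) <- vocab
  colnames(vectors) <- paste0("dim", 1:5)
  space <- structure(
    list(vocabulary = vocab, vectors = vectors,
         singular_values = rep(1, 5), k = 5L, weighting = "us"),
    class = "semantic_space"
  )
  hits <- 0L
  m_total <- 0L
  for (s in 1:4) {
    words <- replicate(60, sample(vocab, 4), simplify = FALSE)
    y <- rnorm(60)
    emb <- suppressMessages(embed_table(words, space))$matrix
    scr <- suppressWarnings(significance_screen(
      space, emb, y, type = "scale", d = 5, n_perm = 120, seed = s
    ))
    hits <- hits + sum(scr$p_raw <= 0.05)
    m_total <- m_total + length(scr$p_raw)
  }
  # super-uniform null: about alpha * m uncorrected rejections at most
  expect_lte(hits, qbinom(0.999, m_total, 0.05) + 1)
})

test_that("alexithymia-by-depression cells partition records", {
  sim <- small_study(1)
  clouds <- suppressWarnings(suppressMessages(
    paq_phq_cells(sim$records, sim$space, d = 10, k = 10)
  ))
  expect_named(clouds, c("lowPAQ_lowPHQ", "lowPAQ_highPHQ",
                         "highPAQ_lowPHQ", "highPAQ_highPHQ"))
  for (cl in clouds) {
    expect_true(all(c("rank", "word", "coefficient", "frequency")
                    %in% names(cl)))
  }
  # force everyone into low PAQ: both high-PAQ clouds are empty
  rec <- sim$records
  rec$paq_total <- pmin(rec$paq_total, 60L)
  w <- testthat::capture_warnings(
    clouds2 <- suppressMessages(
      paq_phq_cells(rec, sim$space, d = 10, k = 10)
    )
  )
  expect_true(any(grepl("degenerate", w)))
  expect_equal(nrow(clouds2$highPAQ_lowPHQ), 0)
  expect_equal(nrow(clouds2$highPAQ_highPHQ), 0)
})
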