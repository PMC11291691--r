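test_that("grouped folds deal whole narratives round-robin, deterministically", {
  plan <- make_grouped_folds(rep(paste0("n", 1:20), each = 3), 10, seed = 4)
  expect_equal(unname(table(plan$assignment)), rep(2L, 10),
               ignore_attr = TRUE)
  plan2 <- make_grouped_folds(rep(paste0("n", 1:20), each = 3), 10, seed = 4)
  expect_identical(plan, plan2)
  plan3 <- make_grouped_folds(rep(paste0("n", 1:20), each = 3), 10, seed = 5)
  expect_false(identical(plan$assignment, plan3$assignment))
  expect_error(make_grouped_folds(paste0("n", 1:5), 10),
               class = "qcla_validation_error")
  expect_error(make_grouped_folds(paste0("n", 1:5), 1),
               class = "qcla_validation_error")
})

test_that("well-separated classes are fit almost perfectly", {
  fs <- planted_feature_set(n_per_class = 25, n_dims = 8, n_signal = 4,
                            sep = 4, seed = 31)
  fit <- fit_multinomial(fs, d = 8)
  pred <- predict_classifier(fit, fs)
  expect_gte(mean(pred$labels == fs$labels), 0.95)
})

test_that("zero features give intercept-only class-frequency probabilities", {
  labels <- factor(rep(emotion_levels(), times = c(10, 20, 30, 40)),
                   levels = emotion_levels())
  fs <- structure(
    list(kind = "words", semantic = matrix(0, 100, 3,
                                           dimnames = list(NULL, paste0("dim", 1:3))),
         scales = NULL, labels = labels,
         groups = as.character(1:100), phase = rep(2L, 100),
         row_id = 1:100),
    class = "feature_set"
  )
  fit <- fit_multinomial(fs, d = 3)
  pred <- predict_classifier(fit, fs)
  freq <- as.numeric(table(labels) / 100)
  expect_equal(unname(pred$prob[1, ]), freq, tolerance = 1e-3)
  expect_equal(unname(rowSums(pred$prob)), rep(1, 100), tolerance = 1e-12)
})

test_that("single-class training is rejected", {
  fs <- planted_feature_set(n_per_class = 10, n_dims = 4, seed = 2)
  expect_error(fit_multinomial(fs, d = 4, rows = 1:10),
               class = "qcla_validation_error")
})

test_that("prediction agrees with a hand-rolled softmax of the coefficients", {
  fs <- planted_feature_set(n_per_class = 15, n_dims = 6, seed = 8)
  fit <- fit_multinomial(fs, d = 6)
  pred <- predict_classifier(fit, fs, rows = 1:10)
  cf <- fit$coefficients
  for (i in 1:10) {
    eta <- as.numeric(cf[, -1, drop = FALSE] %*% fs$semantic[i, ] + cf[, 1])
    p <- exp(eta) / sum(exp(eta))
    expect_equal(unname(pred$prob[i, fit$classes_fit]), unname(p),
                 tolerance = 1e-10)
    expect_equal(as.character(pred$labels[i]),
                 fit$classes_fit[which.max(p)])
  }
})

test_that("exact probability ties break toward the earlier class", {
  clf <- structure(
    list(class_order = emotion_levels(),
         classes_fit = emotion_levels(),
         coefficients = matrix(0, 4, 3,
                               dimnames = list(emotion_levels(),
                                               c("(Intercept)", "dim1", "dim2"))),
         d_selected = 2L, ridge = 0, kind = "words",
         scale_center = NULL, scale_scale = NULL),
    class = "qcla_classifier"
  )
  fs <- structure(
    list(kind = "words",
         semantic = matrix(rnorm(4), 2, 2,
                           dimnames = list(NULL, c("dim1", "dim2"))),
         scales = NULL,
         labels = factor(c("harmony", "anxiety"), levels = emotion_levels()),
         groups = c("a", "b"), phase = c(2L, 2L), row_id = 1:2),
    class = "feature_set"
  )
  pred <- predict_classifier(clf, fs)
  expect_true(all(pred$labels == "harmony"))
  # width mismatch is structural
  clf2 <- clf
  clf2$coefficients <- clf$coefficients[, 1:2]
  expect_error(predict_classifier(clf2, fs), class = "qcla_structural_error")
})

test_that("dimension selection finds a planted low-dimensional signal", {
  fs <- planted_feature_set(n_per_class = 40, n_dims = 30, n_signal = 5,
                            sep = 2.5, seed = 12)
  d <- select_dimensions(fs, grid = c(2, 5, 10, 20, 30), inner_folds = 4,
                         seed = 1)
  expect_lte(d, 10)
  expect_identical(select_dimensions(fs, grid = 7), 7L)
})

test_that("out-of-fold predictions partition the evaluation rows without leakage", {
  sim <- small_study(1)
  fs <- suppressMessages(feature_set(sim$records, "words", sim$space))
  plan <- make_grouped_folds(fs$groups, 5, seed = 2)
  cvp <- suppressMessages(cross_validated_predictions(
    fs, plan = plan, grid = c(5, 15, 30), inner_folds = 3, seed = 2
  ))
  eval_rows <- which(fs$phase == 2L)
  expect_setequal(cvp$row_id, eval_rows)
  expect_equal(anyDuplicated(cvp$row_id), 0L)
  # a row's group always sits in the fold it was scored by
  for (f in unique(cvp$fold)) {
    test_groups <- names(plan$assignment)[plan$assignment == f]
    rows_f <- cvp$row_id[cvp$fold == f]
    expect_true(all(fs$groups[rows_f] %in% test_groups))
    train_groups <- names(plan$assignment)[plan$assignment != f]
    expect_length(intersect(test_groups, train_groups), 0)
  }
  prob_cols <- emotion_levels()
  expect_equal(unname(rowSums(as.matrix(cvp[, prob_cols]))),
               rep(1, nrow(cvp)), tolerance = 1e-9)
})

test_that("accuracy degrades monotonically as word noise rises", {
  accs <- vapply(c(0.05, 0.4, 0.8), function(noise) {
    cfg <- small_config(seed = 19, word_noise_low = noise,
                        word_noise_high = noise)
    sim <- simulate_study(cfg)
    space <- suppressMessages(train_space(sim$corpus, k = 40))
    fs <- suppressMessages(feature_set(sim$records, "words", space))
    cvp <- suppressMessages(cross_validated_predictions(
      fs, n_folds = 5, grid = c(10, 30), inner_folds = 3, seed = 19
    ))
    mean(cvp$pred == cvp$true)
  }, numeric(1))
  expect_true(all(diff(accs) <= 0.02))
})
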