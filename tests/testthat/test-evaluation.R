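test_that("confusion tabulates predicted-by-true counts", {
  perfect <- confusion(emotion_levels(), emotion_levels())
  expect_equal(diag(unclass(perfect)), rep(1L, 4), ignore_attr = TRUE)
  expect_equal(sum(perfect), 4L)
  one <- confusion("depression", "anxiety")
  expect_equal(one["anxiety", "depression"], 1L)
  expect_equal(sum(one), 1L)
  expect_error(confusion("harmony", "joy"), class = "qcla_validation_error")
  expect_error(confusion(c("harmony", "anxiety"), "harmony"),
               class = "qcla_structural_error")
})

test_that("confusion equals a brute-force tally on random label pairs", {
  set.seed(14)
  tr <- sample(emotion_levels(), 200, replace = TRUE)
  pr <- sample(emotion_levels(), 200, replace = TRUE)
  cm <- confusion(tr, pr)
  for (p in emotion_levels()) {
    for (t in emotion_levels()) {
      expect_equal(cm[p, t], sum(pr == p & tr == t))
    }
  }
})

test_that("the published semantic confusion matrix yields its printed metrics", {
  cm <- semantic_confusion_reference()
  m <- metrics_from_confusion(cm)
  h <- m[m$class == "harmony", ]
  expect_equal(round(h$sensitivity, 2), 0.67)
  expect_equal(round(h$precision, 2), 0.59)
  expect_equal(round(h$specificity, 2), 0.89)
  expect_equal(round(h$accuracy, 2), 0.85)
  expect_equal(round(h$f1, 2), 0.63)
  # full panel, both matrices, every defined cell
  expected_sem <- data.frame(
    class = emotion_levels(),
    accuracy = c(0.85, 0.77, 0.77, 0.85),
    precision = c(0.59, 0.76, 0.51, 0.70),
    specificity = c(0.89, 0.94, 0.77, 0.90),
    sensitivity = c(0.67, 0.42, 0.75, 0.71),
    f1 = c(0.63, 0.54, 0.61, 0.71)
  )
  for (col in names(expected_sem)[-1]) {
    expect_equal(round(m[[col]], 2), expected_sem[[col]])
  }
  rs <- metrics_from_confusion(rating_scale_confusion_reference())
  expected_rs <- data.frame(
    class = emotion_levels(),
    accuracy = c(0.73, 0.58, 0.61, 0.74),
    precision = c(0.25, 0.28, 0.37, 0.00),
    specificity = c(0.84, 0.76, 0.51, 0.99),
    sensitivity = c(0.23, 0.20, 0.91, 0.00),
    f1 = c(0.24, 0.24, 0.53, NA)
  )
  for (col in c("accuracy", "precision", "specificity", "sensitivity")) {
    expect_equal(round(rs[[col]], 2), expected_rs[[col]])
  }
  expect_equal(round(rs$f1[1:3], 2), expected_rs$f1[1:3])
  expect_true(is.na(rs$f1[4]))
  expect_equal(format_metrics(rs)$f1[4], "–")
})

test_that("degenerate classes get undefined markers, never zeros", {
  cm <- as_confusion(rbind(c(2, 0, 0, 0), c(0, 3, 0, 0),
                           c(0, 0, 4, 0), c(0, 0, 0, 0)))
  m <- metrics_from_confusion(cm)
  anx <- m[m$class == "anxiety", ]
  expect_true(is.na(anx$precision))
  expect_true(is.na(anx$sensitivity))
  expect_true(is.na(anx$f1))
  ident <- metrics_from_confusion(as_confusion(diag(c(3, 4, 5, 6))))
  for (col in c("accuracy", "precision", "specificity", "sensitivity", "f1")) {
    expect_equal(ident[[col]], rep(1, 4))
  }
})

test_that("overall accuracy is the trace over the grand total", {
  expect_equal(overall_accuracy(as_confusion(diag(4))), 1)
  expect_equal(overall_accuracy(as_confusion(matrix(5, 4, 4))), 0.25)
  expect_equal(round(overall_accuracy(semantic_confusion_reference()), 3),
               0.621)
})

test_that("support-weighted sensitivities equal overall accuracy", {
  set.seed(77)
  for (i in 1:25) {
    cm <- as_confusion(matrix(rpois(16, 6), 4, 4))
    if (sum(cm) == 0) next
    m <- metrics_from_confusion(cm)
    sens <- ifelse(is.na(m$sensitivity), 0, m$sensitivity)
    expect_equal(sum(sens * m$support) / sum(cm), overall_accuracy(cm),
                 tolerance = 1e-12)
  }
})

test_that("proportion comparison matches the four-cell chi-squared formula", {
  eq <- compare_proportions(30, 60, 50, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$effect_size, 0)
  set.seed(6)
  for (i in 1:20) {
    n_a <- sample(30:120, 1); n_b <- sample(30:120, 1)
    c_a <- sample(1:(n_a - 1), 1); c_b <- sample(1:(n_b - 1), 1)
    res <- compare_proportions(c_a, n_a, c_b, n_b)
    obs <- rbind(c(c_a, n_a - c_a), c(c_b, n_b - c_b))
    expe <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    chi2 <- sum((obs - expe)^2 / expe)
    expect_equal(res$statistic, chi2, tolerance = 1e-10)
    expect_equal(res$effect_size, sqrt(chi2 / sum(obs)), tolerance = 1e-10)
    # symmetric in its arguments
    flipped <- compare_proportions(c_b, n_b, c_a, n_a)
    expect_equal(flipped$statistic, res$statistic, tolerance = 1e-10)
  }
  undef <- compare_proportions(0, 10, 0, 10)
  expect_true(is.na(undef$statistic))
})

test_that("the reported-N phi convention is reproducible", {
  expect_equal(round(phi_from_chisq(19.48, 231), 2), 0.29)
  res <- compare_proportions(60, 100, 40, 100, n_phi = 150)
  expect_equal(res$effect_size, sqrt(res$statistic / 150))
})

test_that("pooled t-test matches the closed form and is antisymmetric", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  x <- c(0, 0, 1, 1); y <- c(1, 1, 1, 1)
  # pooled variance: (3*var(x) + 3*var(y)) / 6 = 1/6; se = sqrt(1/6 * 1/2)
  res <- two_sample_t(x, y)
  expect_equal(res$df, 6)
  expect_equal(res$statistic, (0.5 - 1) / sqrt((1 / 6) * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
  swap <- two_sample_t(y, x)
  expect_equal(swap$statistic, -res$statistic)
  expect_equal(swap$p_value, res$p_value)
  undef <- two_sample_t(c(2, 2, 2), c(2, 2))
  expect_true(is.na(undef$statistic))
})

test_that("variance F-test matches its closed forms and a quadrature oracle", {
  expect_equal(variance_f_test(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  set.seed(10)
  x <- rnorm(15)
  y <- 2 * (x - mean(x)) + mean(x)
  expect_equal(variance_f_test(x, y)$statistic, 0.25, tolerance = 1e-12)
  a <- rnorm(12); b <- rnorm(17, sd = 1.7)
  res <- variance_f_test(a, b)
  f_obs <- var(a) / var(b)
  upper <- integrate(function(q) df(q, 11, 16), f_obs, Inf)$value
  p_orc <- 2 * min(upper, 1 - upper)
  expect_equal(res$p_value, p_orc, tolerance = 1e-6)
  expect_true(is.na(variance_f_test(c(1, 1, 1), a)$statistic))
})

test_that("pearson matches the covariance formula with a t-based p", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  set.seed(23)
  a <- rnorm(100); b <- 0.4 * a + rnorm(100)
  res <- pearson(a, b)
  r_orc <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, r_orc, tolerance = 1e-12)
  tstat <- r_orc * sqrt(98 / (1 - r_orc^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 98), tolerance = 1e-12)
  expect_true(is.na(pearson(rep(1, 5), x)$r))
})

test_that("Bonferroni flags are a subset of uncorrected flags", {
  expect_equal(bonferroni(c(0.01, 0.04), 0.05), c(TRUE, FALSE))
  expect_equal(bonferroni(0.04, 0.05), TRUE)
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    flags <- bonferroni(p, 0.05)
    expect_true(all(!flags | (p <= 0.05)))
  }
  expect_error(bonferroni(c(0.2, 1.4)), class = "qcla_validation_error")
})
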