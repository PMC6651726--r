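test_that("confusion metrics implement the braking-positive definitions", {
  m <- confusion_metrics(rep(c("braking", "normal"), c(50, 50)),
                         rep(c("braking", "normal"), c(50, 50)))
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  y <- rep(c("braking", "normal"), c(10, 90))
  m2 <- confusion_metrics(y, rep("normal", 100))
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
  expect_equal(m2$accuracy, 0.9)

  # degenerate denominators come back NA, not NaN
  m3 <- confusion_metrics(rep("normal", 5), rep("normal", 5))
  expect_true(is.na(m3$sensitivity))
  expect_error(confusion_metrics(character(0), character(0)), "empty")
})

test_that("random-label metrics equal direct pair counting", {
  withr::with_seed(20, {
    y <- sample(c("normal", "braking"), 200, replace = TRUE)
    p <- sample(c("normal", "braking"), 200, replace = TRUE)
  })
  m <- confusion_metrics(y, p)
  expect_equal(m$accuracy, mean(y == p))
  expect_equal(m$sensitivity, mean(p[y == "braking"] == "braking"))
  expect_equal(m$specificity, mean(p[y == "normal"] == "normal"))
  expect_equal(m$tp + m$tn + m$fp + m$fn, 200)
})

test_that("AUC equals the normalized Mann-Whitney statistic, ties included", {
  withr::with_seed(21, {
    y <- rep(c("braking", "normal"), c(14, 16))
    s <- round(c(rnorm(14, 1), rnorm(16)), 1) # rounding forces ties
  })
  roc <- roc_curve_auc(y, s)
  expect_equal(roc$auc, auc_paircount(y, s), tolerance = 1e-12)

  perfect <- roc_curve_auc(y, as.numeric(y == "braking"))
  expect_equal(perfect$auc, 1)

  withr::with_seed(22, {
    y2 <- rep(c("braking", "normal"), each = 500)
    s2 <- runif(1000)
  })
  expect_lt(abs(roc_curve_auc(y2, s2)$auc - 0.5), 0.05)
  expect_error(roc_curve_auc(rep("normal", 5), runif(5)), "both classes")
})

test_that("stratified folds partition every sample with balanced sizes", {
  labels <- rep(c("normal", "braking"), c(922, 496))
  fold <- brakeintent:::stratified_folds(labels, 5, seed = 1)
  sizes <- as.integer(table(fold))
  expect_identical(sort(sizes, decreasing = TRUE), c(284L, 284L, 284L, 283L, 283L))
  expect_equal(sum(sizes), 1418)
  # class ratio preserved within one sample per fold
  per_class <- table(fold, labels)
  expect_lte(diff(range(per_class[, "braking"])), 1)
  expect_lte(diff(range(per_class[, "normal"])), 1)
  expect_identical(fold, brakeintent:::stratified_folds(labels, 5, seed = 1))
})

test_that("cross-validation holds out every sample exactly once", {
  ds <- toy_dataset(n_per_class = 40, gap = 2, seed = 30)
  cv <- kfold_cv(ds, k = 5, config = mlp_config(n_hidden = 5, max_iterations = 40), seed = 2)
  expect_equal(nrow(cv$predictions), nrow(ds))
  expect_equal(sort(cv$predictions$window_end_s), sort(ds$window_end_s))
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(cv$folds$n_val %in% 15:17))
  cv2 <- kfold_cv(ds, k = 5, config = mlp_config(n_hidden = 5, max_iterations = 40), seed = 2)
  expect_identical(cv$folds, cv2$folds)
  expect_error(kfold_cv(ds[c(1:3, 41:80), ], k = 5), "smallest class")
})

test_that("a one-point sweep reduces to a single cross-validation", {
  sess <- fixture_session()
  sw <- sweep_parameter(sess, "ar_order", 6, step_ms = 250, k = 3,
                        use_ica = FALSE, seed = 5)
  ds <- build_dataset(sess, step_ms = 250, feature = "ar", ar_order = 6,
                      use_ica = FALSE, seed = 5)
  cv <- kfold_cv(ds, k = 3, seed = 5)
  expect_equal(nrow(sw), 3)
  expect_equal(sw$accuracy, cv$folds$accuracy)
  expect_equal(tidy(sw)$mean_auc, mean(cv$folds$auc))
  expect_error(sweep_parameter(sess, "ar_order", numeric(0)), "empty")
})
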