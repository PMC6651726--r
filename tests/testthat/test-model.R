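test_that("network initialization is seeded and shape-checked", {
  n1 <- init_network(80, mlp_config(n_hidden = 50, seed = 3))
  n2 <- init_network(80, mlp_config(n_hidden = 50, seed = 3))
  expect_identical(n1$w1, n2$w1)
  expect_identical(dim(n1$w1), c(50L, 80L))
  expect_identical(dim(n1$w2), c(2L, 50L))
  expect_error(mlp_config(n_hidden = 0), "positive")
})

test_that("the softmax forward pass is normalized, symmetric and stable", {
  net <- init_network(4, mlp_config(n_hidden = 8, seed = 1))
  p <- forward(net, rnorm(4))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(forward(net, rnorm(5)), "length")

  # symmetric pre-activations give 0.5/0.5; huge ones must not overflow
  z <- matrix(c(0, 0, 1000, 0), 2, byrow = TRUE)
  sm <- brakeintent:::softmax_rows(z)
  expect_equal(sm[1, ], c(0.5, 0.5))
  expect_equal(sm[2, ], c(1, 0))
  expect_true(all(is.finite(sm)))
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(7, {
    x <- matrix(rnorm(12 * 5), 12)
    y <- cbind(rbinom(12, 1, 0.5), 0)
    y[, 2] <- 1 - y[, 1]
    net <- init_network(5, mlp_config(n_hidden = 3, seed = 2))
    g <- brakeintent:::mlp_gradients(net, x, y)
    eps <- 1e-6
    for (nm in c("w1", "b1", "w2", "b2")) {
      idx <- sample(length(net[[nm]]), min(6, length(net[[nm]])))
      for (i in idx) {
        up <- net; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- net; dn[[nm]][i] <- dn[[nm]][i] - eps
        lu <- brakeintent:::mlp_gradients(up, x, y)$loss
        ld <- brakeintent:::mlp_gradients(dn, x, y)$loss
        fd <- (lu - ld) / (2 * eps)
        denom <- max(abs(fd), abs(g[[nm]][i]), 1e-8)
        expect_lt(abs(fd - g[[nm]][i]) / denom, 1e-6)
      }
    }
  })
})

test_that("training separates a linearly separable toy problem", {
  ds <- toy_dataset(gap = 3, seed = 5)
  net <- fit_mlp(ds, config = mlp_config(n_hidden = 50, max_iterations = 200, seed = 1))
  pred <- predict(net, ds)
  expect_equal(mean(pred$.pred_class == ds$label), 1)
  expect_lte(nrow(net$history), 200)
  # adaptive full-batch descent: the loss curve is non-increasing up to
  # the occasional probing step that the step-size halving undoes
  drops <- diff(net$history$train_loss)
  expect_lt(mean(drops > 0), 0.2)
  expect_lt(tail(net$history$train_loss, 1), head(net$history$train_loss, 1))
})

test_that("label-shuffled data trains to chance", {
  ds <- toy_dataset(gap = 0, seed = 8) # no class signal at all
  cv <- kfold_cv(ds, k = 5, config = mlp_config(n_hidden = 10, max_iterations = 60), seed = 2)
  expect_lt(abs(glance(cv)$pooled_accuracy - 0.5), 0.15)
})

test_that("degenerate training inputs are rejected", {
  ds <- toy_dataset(seed = 3)
  only_normal <- ds[ds$label == "normal", ]
  expect_error(train_network(NULL, only_normal), "both classes")
})

test_that("prediction breaks exact ties toward normal", {
  net <- init_network(2, mlp_config(n_hidden = 4, seed = 1))
  # zero weights force softmax(0, 0) = (0.5, 0.5)
  net$w1[] <- 0; net$b1[] <- 0; net$w2[] <- 0; net$b2[] <- 0
  net$trained <- TRUE
  p <- predict(net, matrix(rnorm(6), 3))
  expect_equal(p$.pred_braking, rep(0.5, 3))
  expect_true(all(p$.pred_class == "normal"))
})

test_that("checkpoints restore the exact model", {
  ds <- toy_dataset(seed = 9)
  net <- fit_mlp(ds, config = mlp_config(n_hidden = 10, max_iterations = 50, seed = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(net, path)
  back <- read_checkpoint(path)
  expect_identical(back$w1, net$w1)
  expect_identical(back$center, net$center)
  expect_identical(predict(back, ds), predict(net, ds))
  expect_error(read_checkpoint(withr::local_tempfile(lines = "x")), "checkpoint")
})

test_that("an independent single-hidden-layer implementation agrees on a toy task", {
  ds <- toy_dataset(gap = 2, seed = 11)
  net <- fit_mlp(ds, config = mlp_config(n_hidden = 10, max_iterations = 100, seed = 1))
  acc_mine <- mean(predict(net, ds)$.pred_class == ds$label)
  ref <- nnet::nnet(feature_matrix(ds), nnet::class.ind(ds$label), size = 10,
                    softmax = TRUE, trace = FALSE, maxit = 100)
  acc_ref <- mean(max.col(stats::predict(ref, feature_matrix(ds))) ==
                    as.integer(ds$label))
  expect_gt(acc_mine, 0.95)
  expect_gt(acc_ref, 0.95)
})

test_that("tidiers summarise fitted networks", {
  ds <- toy_dataset(seed = 12)
  val <- toy_dataset(seed = 13)
  net <- train_network(NULL, ds, val, mlp_config(n_hidden = 5, max_iterations = 80))
  td <- tidy(net)
  expect_true(all(c("iteration", "set", "cross_entropy") %in% names(td)))
  expect_setequal(unique(td$set), c("train", "validation"))
  gl <- glance(net)
  expect_equal(gl$n_hidden, 5)
  expect_lt(gl$val_loss, Inf)
})
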