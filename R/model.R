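#' Network configuration for the three-layer perceptron
#'
#' @param n_hidden Hidden-layer width; 10, 20, 50, 100, 500, 1000 in the
#'   standard sweep, default 50.
#' @param max_iterations Full-batch gradient iterations (default 200).
#' @param patience Early stopping: stop when validation cross-entropy has not
#'   improved for this many iterations (default 10); ignored without a
#'   validation set.
#' @param learning_rate Initial step size of the adaptive full-batch descent.
#' @param seed Seed for the weight initialization.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(n_hidden = 50, max_iterations = 200, patience = 10,
                       learning_rate = 0.5, seed = 1L) {
  if (!is.numeric(n_hidden) || n_hidden <= 0) stop("`n_hidden` must be a positive count")
  stopifnot(max_iterations >= 1, learning_rate > 0)
  structure(
    list(n_hidden = as.integer(n_hidden),
         max_iterations = as.integer(max_iterations),
         patience = as.integer(patience),
         learning_rate = learning_rate,
         seed = as.integer(seed)),
    class = "mlp_config"
  )
}

#' Initialize an untrained three-layer perceptron
#'
#' Input layer of width D (40 band-power or 8 x (AR order + 1) inputs), sigmoid
#' hidden layer, 2-unit softmax output (class order: normal = 1, braking = 2).
#' Weights are symmetric-uniform scaled by fan-in, seeded.
#'
#' @param n_input Input dimension D.
#' @param config An [mlp_config()].
#' @return A `brake_mlp` (untrained: no standardization constants yet).
#' @export
init_network <- function(n_input, config = mlp_config()) {
  stopifnot(inherits(config, "mlp_config"), n_input >= 1)
  h <- config$n_hidden
  withr::with_seed(config$seed, {
    w1 <- matrix(stats::runif(h * n_input, -1, 1) / sqrt(n_input), h, n_input)
    b1 <- numeric(h)
    w2 <- matrix(stats::runif(2 * h, -1, 1) / sqrt(h), 2, h)
    b2 <- numeric(2)
  })
  structure(
    list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
         config = config, n_input = n_input,
         center = NULL, scale = NULL, feature_names = NULL,
         history = tibble::tibble(iteration = integer(0),
                                  train_loss = numeric(0),
                                  val_loss = numeric(0)),
         trained = FALSE),
    class = "brake_mlp"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max) # max-subtraction: stable for large pre-activations
  ez <- exp(z)
  ez / rowSums(ez)
}

mlp_forward_raw <- function(net, x) {
  a1 <- sigmoid(x %*% t(net$w1) + rep(net$b1, each = nrow(x)))
  z2 <- a1 %*% t(net$w2) + rep(net$b2, each = nrow(x))
  list(a1 = a1, prob = softmax_rows(z2))
}

#' Forward pass: class probabilities for one feature vector
#'
#' @param network A `brake_mlp`.
#' @param x Numeric vector of length `n_input` (already standardized if the
#'   network is untrained; trained networks apply their stored constants).
#' @return Length-2 probability vector `(normal, braking)`, summing to 1.
#' @export
forward <- function(network, x) {
  stopifnot(inherits(network, "brake_mlp"))
  if (length(x) != network$n_input) {
    stop(sprintf("input has length %d, network expects %d", length(x), network$n_input))
  }
  xm <- matrix(x, nrow = 1)
  if (!is.null(network$center)) {
    xm <- (xm - rep(network$center, each = 1)) / rep(network$scale, each = 1)
  }
  p <- mlp_forward_raw(network, xm)$prob[1, ]
  stats::setNames(p, c("normal", "braking"))
}

cross_entropy <- function(prob, y_onehot) {
  -mean(rowSums(y_onehot * log(pmax(prob, 1e-300))))
}

mlp_gradients <- function(net, x, y_onehot) {
  n <- nrow(x)
  fwd <- mlp_forward_raw(net, x)
  d2 <- (fwd$prob - y_onehot) / n          # softmax + cross-entropy
  gw2 <- t(d2) %*% fwd$a1
  gb2 <- colSums(d2)
  d1 <- (d2 %*% net$w2) * fwd$a1 * (1 - fwd$a1)
  gw1 <- t(d1) %*% x
  gb1 <- colSums(d1)
  list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2, loss = cross_entropy(fwd$prob, y_onehot))
}

#' Train the perceptron on a labeled dataset
#'
#' Full-batch gradient descent on the mean cross-entropy with an adaptive
#' step (grow the step after an improving iteration, halve it after a
#' worsening one) — deterministic for a fixed seed and
#' invariant to sample order. Features are z-scored with constants computed
#' from the training set only and stored in the model. With a validation set,
#' training stops early when validation cross-entropy fails to improve for
#' `patience` iterations, and the best-validation weights are kept.
#'
#' @param network A `brake_mlp` from [init_network()], or `NULL` to
#'   initialize from `config` and the data dimension.
#' @param train A `brake_dataset` (both classes must be present).
#' @param val Optional validation `brake_dataset`.
#' @param config Used when `network` is `NULL`.
#' @return A trained `brake_mlp` with `history` (per-iteration train and
#'   validation cross-entropy).
#' @export
train_network <- function(network = NULL, train, val = NULL,
                          config = mlp_config()) {
  x <- feature_matrix(train)
  y <- train$label
  if (nlevels(droplevels(y)) < 2) stop("training set must contain both classes")
  if (is.null(network)) network <- init_network(ncol(x), config)
  stopifnot(ncol(x) == network$n_input)

  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  y_onehot <- cbind(normal = y == "normal", braking = y == "braking") * 1

  has_val <- !is.null(val)
  if (has_val) {
    xv <- sweep(sweep(feature_matrix(val), 2, center), 2, scl, "/")
    yv <- cbind(normal = val$label == "normal", braking = val$label == "braking") * 1
  }

  net <- network
  lrate <- net$config$learning_rate
  hist_train <- hist_val <- numeric(0)
  best_val <- Inf
  best_net <- NULL
  stall <- 0
  prev_loss <- Inf
  for (it in seq_len(net$config$max_iterations)) {
    g <- mlp_gradients(net, xs, y_onehot)
    if (g$loss > prev_loss) {
      lrate <- lrate / 2
    } else {
      lrate <- lrate * 1.05
    }
    prev_loss <- g$loss
    net$w1 <- net$w1 - lrate * g$w1
    net$b1 <- net$b1 - lrate * g$b1
    net$w2 <- net$w2 - lrate * g$w2
    net$b2 <- net$b2 - lrate * g$b2
    hist_train <- c(hist_train, g$loss)
    if (has_val) {
      vloss <- cross_entropy(mlp_forward_raw(net, xv)$prob, yv)
      hist_val <- c(hist_val, vloss)
      if (vloss < best_val - 1e-9) {
        best_val <- vloss
        best_net <- net[c("w1", "b1", "w2", "b2")]
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= net$config$patience) break
      }
    }
  }
  if (has_val && !is.null(best_net)) net[names(best_net)] <- best_net
  net$center <- center
  net$scale <- scl
  net$feature_names <- feature_cols(train)
  net$history <- tibble::tibble(
    iteration = seq_along(hist_train),
    train_loss = hist_train,
    val_loss = if (has_val) hist_val else NA_real_
  )
  net$trained <- TRUE
  net
}

#' Fit a perceptron in one call
#' @inheritParams train_network
#' @export
fit_mlp <- function(train, val = NULL, config = mlp_config()) {
  train_network(NULL, train, val, config)
}

#' Predict classes and braking probabilities for a dataset
#'
#' Argmax of the softmax output; an exact 0.5/0.5 tie goes to `normal` (the
#' lower class index). The braking-class probability is the ROC score.
#'
#' @param object A trained `brake_mlp`.
#' @param newdata A `brake_dataset` (or tibble with the same feature columns).
#' @param ... Unused.
#' @return Tibble: `.pred_class` (factor normal/braking), `.pred_braking`
#'   (probability of the braking class).
#' @export
predict.brake_mlp <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (ncol(x) != object$n_input) {
    stop(sprintf("newdata has %d feature columns, network expects %d",
                 ncol(x), object$n_input))
  }
  if (!is.null(object$center)) {
    x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  }
  prob <- mlp_forward_raw(object, x)$prob
  tibble::tibble(
    .pred_class = factor(ifelse(prob[, 2] > prob[, 1], "braking", "normal"),
                         levels = c("normal", "braking")),
    .pred_braking = prob[, 2]
  )
}

#' @export
print.brake_mlp <- function(x, ...) {
  cat(sprintf(
    "<brake_mlp> %d-%d-2 (sigmoid hidden, softmax output)%s\n",
    x$n_input, x$config$n_hidden,
    if (x$trained) sprintf(" | trained %d iterations, final CE %.4f",
                           nrow(x$history), utils::tail(x$history$train_loss, 1))
    else " | untrained"
  ))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries weights, configuration, feature-standardization
#' constants and the feature layout, so a streaming detector can reload it
#' and verify its input contract.
#'
#' @param network A trained `brake_mlp`.
#' @param path File path.
#' @return `write_checkpoint()` returns `path` invisibly; `read_checkpoint()`
#'   a `brake_mlp`.
#' @export
write_checkpoint <- function(network, path) {
  stopifnot(inherits(network, "brake_mlp"))
  saveRDS(c(list(schema = "brakeintent-mlp-v1"), unclass(network)), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (!is.list(obj) || !identical(obj$schema, "brakeintent-mlp-v1")) {
    stop("not a brakeintent model checkpoint")
  }
  obj$schema <- NULL
  structure(obj, class = "brake_mlp")
}
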