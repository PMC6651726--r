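#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted perceptron
#'
#' @param x A trained `brake_mlp`.
#' @param ... Unused.
#' @return Long tibble: `iteration`, `set` (train/validation), `cross_entropy`.
#' @exportS3Method generics::tidy
tidy.brake_mlp <- function(x, ...) {
  h <- x$history
  out <- tidyr::pivot_longer(h, cols = c("train_loss", "val_loss"),
                             names_to = "set", values_to = "cross_entropy")
  out$set <- ifelse(out$set == "train_loss", "train", "validation")
  dplyr::filter(out, !is.na(.data$cross_entropy))
}

#' One-row summary of a fitted perceptron
#'
#' @param x A trained `brake_mlp`.
#' @param ... Unused.
#' @return Tibble: `n_input`, `n_hidden`, `n_iterations`, `train_loss`
#'   (final), `val_loss` (best, NA without a validation set).
#' @exportS3Method generics::glance
glance.brake_mlp <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_hidden = x$config$n_hidden,
    n_iterations = nrow(x$history),
    train_loss = if (nrow(x$history)) utils::tail(x$history$train_loss, 1) else NA_real_,
    val_loss = if (all(is.na(x$history$val_loss))) NA_real_ else min(x$history$val_loss, na.rm = TRUE)
  )
}

#' Per-fold metrics of a cross-validation run
#' @param x A `brake_cv`.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @exportS3Method generics::tidy
tidy.brake_cv <- function(x, ...) x$folds

#' Fold-averaged and pooled summary of a cross-validation run
#'
#' Both aggregations are reported: the mean (+/- sd) over fold-level metrics
#' and the metrics of the pooled out-of-fold predictions.
#'
#' @param x A `brake_cv`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.brake_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    mean_accuracy = mean(x$folds$accuracy),
    sd_accuracy = stats::sd(x$folds$accuracy),
    mean_sensitivity = mean(x$folds$sensitivity),
    mean_specificity = mean(x$folds$specificity),
    mean_auc = mean(x$folds$auc),
    sd_auc = stats::sd(x$folds$auc),
    pooled_accuracy = x$pooled$accuracy,
    pooled_auc = x$pooled$auc
  )
}

#' Per-value summary of a parameter sweep
#' @param x A `brake_sweep`.
#' @param ... Unused.
#' @return Tibble: one row per grid value with mean/sd accuracy and AUC.
#' @exportS3Method generics::tidy
tidy.brake_sweep <- function(x, ...) attr(x, "summary")
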