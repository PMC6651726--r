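#' Confusion-matrix metrics with braking as the positive class
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN), sensitivity = TP / (TP + FN)
#' (braking recall), specificity = TN / (TN + FP) (normal recall). A metric
#' whose denominator is zero is returned as `NA` (marked undefined, never
#' propagated as NaN).
#'
#' @param y_true,y_pred Equal-length factors or characters with levels
#'   normal/braking.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `tp`,
#'   `tn`, `fp`, `fn`, `n`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0) stop("empty label vectors")
  y_true <- factor(as.character(y_true), levels = c("normal", "braking"))
  y_pred <- factor(as.character(y_pred), levels = c("normal", "braking"))
  tp <- sum(y_true == "braking" & y_pred == "braking")
  tn <- sum(y_true == "normal" & y_pred == "normal")
  fp <- sum(y_true == "normal" & y_pred == "braking")
  fn <- sum(y_true == "braking" & y_pred == "normal")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    tp = tp, tn = tn, fp = fp, fn = fn, n = length(y_true)
  )
}

#' ROC curve and AUC from braking-class scores
#'
#' Sweeps all score thresholds, with tied scores grouped, and integrates the
#' curve by the trapezoid rule — equivalent to the normalized Mann-Whitney U
#' statistic with ties counted one half.
#'
#' @param y_true Labels (normal/braking); both classes required.
#' @param scores Braking-class probabilities or any monotone score.
#' @return List of class `brake_roc`: `curve` (tibble `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_curve_auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  y <- factor(as.character(y_true), levels = c("normal", "braking"))
  n_pos <- sum(y == "braking")
  n_neg <- sum(y == "normal")
  if (n_pos == 0 || n_neg == 0) stop("ROC needs both classes in `y_true`")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- y[ord] == "braking"
  # group ties: one ROC vertex per distinct score
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp[last] / n_pos),
    fpr = c(0, fp[last] / n_neg)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "brake_roc")
}

#' @export
print.brake_roc <- function(x, ...) {
  cat(sprintf("<brake_roc> %d thresholds | AUC = %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

# stratified fold assignment reproducing balanced fold totals: per-class
# remainders are handed to the folds with the smallest running totals
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  fold <- integer(n)
  totals <- integer(k)
  withr::with_seed(as.integer(seed), {
    for (cl in levels(factor(labels))) {
      idx <- sample(which(labels == cl))
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      sizes <- rep(base, k)
      if (extra > 0) {
        gets <- order(totals, seq_len(k))[seq_len(extra)]
        sizes[gets] <- sizes[gets] + 1
      }
      stop_at <- cumsum(sizes)
      start_at <- c(1, utils::head(stop_at, -1) + 1)
      for (f in seq_len(k)) {
        if (sizes[f] > 0) fold[idx[start_at[f]:stop_at[f]]] <- f
      }
      totals <- totals + sizes
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the full classifier
#'
#' Samples are shuffled, then split into k stratified folds (class ratio
#' preserved within one sample per fold). Each fold serves as validation
#' exactly once; feature-standardization constants are fit on each training
#' fold only. Reports per-fold metrics plus pooled metrics over the
#' out-of-fold predictions.
#'
#' @param data A `brake_dataset`.
#' @param k Number of folds (default 5).
#' @param config An [mlp_config()].
#' @param seed Seed controlling the fold assignment and weight init.
#' @return A `brake_cv`: list with `folds` (tibble of per-fold `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `n_val`), `pooled` (metrics over
#'   all out-of-fold predictions), `predictions` (per-sample out-of-fold
#'   tibble), `k`, `config`.
#' @export
kfold_cv <- function(data, k = 5, config = mlp_config(), seed = 1L) {
  y <- data$label
  if (min(table(y)) < k) stop("`k` exceeds the size of the smallest class")
  fold <- stratified_folds(y, k, seed)
  fold_rows <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- data[fold != f, , drop = FALSE]
    va <- data[fold == f, , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + f # independent init per fold
    net <- train_network(NULL, tr, va, cfg)
    p <- predict(net, va)
    m <- confusion_metrics(va$label, p$.pred_class)
    roc <- roc_curve_auc(va$label, p$.pred_braking)
    fold_rows[[f]] <- dplyr::mutate(
      dplyr::select(m, "accuracy", "sensitivity", "specificity"),
      auc = roc$auc, n_val = nrow(va), fold = f, .before = 1
    )
    preds[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, label = va$label, window_end_s = va$window_end_s), p
    )
  }
  predictions <- dplyr::bind_rows(preds)
  pooled <- dplyr::mutate(
    confusion_metrics(predictions$label, predictions$.pred_class),
    auc = roc_curve_auc(predictions$label, predictions$.pred_braking)$auc
  )
  structure(
    list(folds = dplyr::bind_rows(fold_rows), pooled = pooled,
         predictions = predictions, k = k, config = config, seed = seed),
    class = "brake_cv"
  )
}

#' @export
print.brake_cv <- function(x, ...) {
  cat(sprintf(
    "<brake_cv> %d-fold | mean accuracy %.3f (sd %.3f) | mean AUC %.3f | pooled accuracy %.3f\n",
    x$k, mean(x$folds$accuracy), stats::sd(x$folds$accuracy),
    mean(x$folds$auc), x$pooled$accuracy
  ))
  invisible(x)
}

#' Sweep one pipeline parameter over a grid
#'
#' Re-runs the pipeline and [kfold_cv()] at every grid value. Parameters that
#' change the labeling or windowing (`step_ms`, `pre_braking_ms`) trigger
#' re-segmentation and re-labeling of the session, exactly as the training
#' mode would; `ar_order` and `n_hidden` reuse the same windows.
#'
#' @param session A `brake_session`.
#' @param parameter One of `"ar_order"`, `"step_ms"`, `"pre_braking_ms"`,
#'   `"n_hidden"`.
#' @param values Grid of values (non-empty).
#' @param feature Feature family for the sweep (`"ar"` or `"bandpower"`).
#' @param step_ms,ar_order Baseline values for the parameters not swept.
#' @param config A [labeling_config()] baseline.
#' @param mlp An [mlp_config()] baseline.
#' @param k Folds per grid point.
#' @param use_ica Run ICA artifact cleaning during featurization.
#' @param seed Seed shared by all grid points.
#' @return A `brake_sweep` tibble: one row per (value, fold) with metrics,
#'   plus attributes `parameter` and `summary` (mean +/- sd per value).
#' @export
sweep_parameter <- function(session, parameter, values, feature = "ar",
                            step_ms = 125, ar_order = 10,
                            config = labeling_config(), mlp = mlp_config(),
                            k = 5, use_ica = TRUE, seed = 1L) {
  parameter <- match.arg(parameter, c("ar_order", "step_ms", "pre_braking_ms", "n_hidden"))
  if (length(values) == 0) stop("empty sweep grid")
  rows <- list()
  for (v in values) {
    cfg <- config
    mcfg <- mlp
    this_step <- step_ms
    this_order <- ar_order
    if (parameter == "step_ms") this_step <- v
    if (parameter == "pre_braking_ms") cfg$pre_braking_ms <- v
    if (parameter == "ar_order") this_order <- v
    if (parameter == "n_hidden") mcfg$n_hidden <- as.integer(v)
    ds <- build_dataset(session, step_ms = this_step, feature = feature,
                        ar_order = this_order, config = cfg,
                        use_ica = use_ica, seed = seed)
    cv <- kfold_cv(ds, k = k, config = mcfg, seed = seed)
    rows[[length(rows) + 1]] <- dplyr::mutate(cv$folds, value = v, .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(out, .data$value),
    mean_accuracy = mean(.data$accuracy), sd_accuracy = stats::sd(.data$accuracy),
    mean_auc = mean(.data$auc), sd_auc = stats::sd(.data$auc),
    .groups = "drop"
  )
  structure(out, parameter = parameter, summary = summary,
            class = c("brake_sweep", class(out)))
}
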