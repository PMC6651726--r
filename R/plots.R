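#' Plot a stretch of raw session signals
#'
#' EEG channels stacked with a fixed vertical offset above the IMU magnitude
#' traces, with executed braking events marked.
#'
#' @param object A `brake_session`.
#' @param from_s,to_s Time range to draw (defaults to the first 30 s).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.brake_session <- function(object, from_s = 0,
                                   to_s = min(30, session_duration(object)), ...) {
  fs <- object$fs
  idx <- (floor(from_s * fs) + 1):min(ncol(object$eeg), ceiling(to_s * fs))
  t <- idx / fs
  offset <- 6 * stats::sd(object$eeg[, idx])
  eeg_df <- purrr::map_dfr(seq_len(8), function(ch) {
    tibble::tibble(time_s = t, channel = object$channel_names[ch],
                   value = object$eeg[ch, idx] + (8 - ch) * offset)
  })
  p <- ggplot2::ggplot(eeg_df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                            group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "EEG (stacked, µV)",
                  title = "Session EEG with executed braking events") +
    ggplot2::theme_minimal()
  if (!is.null(object$truth_events)) {
    ev <- object$truth_events$braking_time_s
    ev <- ev[ev >= from_s & ev <= to_s]
    if (length(ev)) {
      p <- p + ggplot2::geom_vline(xintercept = ev, colour = "red",
                                   linetype = "dashed", linewidth = 0.3)
    }
  }
  p
}

#' Plot training and validation loss curves
#' @param object A trained `brake_mlp`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.brake_mlp <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$cross_entropy,
                               colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "cross-entropy",
                  title = "Perceptron training history", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#' @param object A `brake_roc` from [roc_curve_auc()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.brake_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep as mean accuracy and AUC with fold spread
#' @param object A `brake_sweep`.
#' @param metric `"accuracy"` or `"auc"`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.brake_sweep <- function(object, metric = c("accuracy", "auc"), ...) {
  metric <- match.arg(metric)
  s <- tidy(object)
  mcol <- paste0("mean_", metric)
  scol <- paste0("sd_", metric)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$value, y = .data[[mcol]])) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[mcol]] - .data[[scol]],
      ymax = .data[[mcol]] + .data[[scol]]
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(object, "parameter"),
                  y = sprintf("cross-validated %s (mean ± sd)", metric)) +
    ggplot2::theme_minimal()
}

#' Plot streaming braking probability with events and detections
#' @param object A `brake_stream`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.brake_stream <- function(object, ...) {
  p <- ggplot2::ggplot(object$predictions,
                       ggplot2::aes(x = .data$time_s, y = .data$.pred_braking)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "P(braking intention)",
                  title = "Streaming detector output") +
    ggplot2::theme_minimal()
  if (length(object$events)) {
    p <- p + ggplot2::geom_vline(xintercept = object$events, colour = "red",
                                 linetype = "dashed", linewidth = 0.3)
  }
  det <- object$detections$detection_time_s
  if (length(det)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(time_s = det, .pred_braking = 1),
      colour = "blue", shape = 17
    )
  }
  p
}
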