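#' Simulated real-time detection over a session
#'
#' Replays the session through a rolling 1-s buffer: after a 1-s warm-up,
#' `step_ms` of new samples are appended at each step and the oldest samples
#' dropped, and the current buffer is preprocessed, featurized and classified
#' exactly as in training — so streaming predictions are bit-identical to
#' batch analysis of the same session at the same step size. A detection
#' fires when `smoothing_n` consecutive steps predict braking; its time is
#' the buffer-end time of the step completing the run.
#'
#' @param session A `brake_session` of at least 1 s.
#' @param network A trained `brake_mlp` (or a checkpoint path).
#' @param step_ms Step size in ms (default 62.5 = 8 samples at 128 Hz).
#' @param smoothing_n Consecutive braking predictions required to fire a
#'   detection (default 2; 1 reproduces undebounced per-window firing).
#' @param feature,ar_order,use_ica,apen_threshold Featurization settings;
#'   must match the checkpoint's input size.
#' @param seed Base seed for per-window ICA (same convention as training).
#' @return A `brake_stream`: list with `predictions` (tibble `time_s`,
#'   `.pred_class`, `.pred_braking`), `detections` (tibble `detection_time_s`,
#'   `event_time_s`, `lead_time_ms`; `event_time_s` is the matched IMU-detected
#'   braking event, NA for a false alarm), `step_ms`, `events` (IMU-detected
#'   event times used as reference).
#' @export
stream_detect <- function(session, network, step_ms = 62.5, smoothing_n = 2,
                          feature = c("ar", "bandpower"), ar_order = 10,
                          use_ica = TRUE, apen_threshold = 0.35, seed = 1L) {
  feature <- match.arg(feature)
  if (is.character(network)) network <- read_checkpoint(network)
  stopifnot(inherits(network, "brake_mlp"), network$trained)
  fs <- session$fs
  step_n <- step_ms / 1000 * fs
  if (abs(step_n - round(step_n)) > 1e-9) {
    stop("`step_ms` must be a multiple of the sample period (1000/fs ms)")
  }
  step_n <- as.integer(round(step_n))
  win_n <- as.integer(fs)
  n <- ncol(session$eeg)
  if (n < win_n) stop("session shorter than the 1-s analysis buffer")

  expected_d <- if (feature == "ar") 8L * (ar_order + 1L) else 40L
  if (network$n_input != expected_d) {
    stop(sprintf("checkpoint expects %d inputs but %s featurization yields %d",
                 network$n_input, feature, expected_d))
  }

  buffer <- session$eeg[, seq_len(win_n), drop = FALSE]
  next_sample <- win_n
  times <- numeric(0)
  probs <- numeric(0)
  run <- 0
  det_times <- numeric(0)
  repeat {
    t_end <- next_sample / fs
    x <- preprocess_window(buffer, fs = fs, start_time_s = t_end - win_n / fs,
                           use_ica = use_ica, apen_threshold = apen_threshold,
                           seed = seed)
    vec <- if (feature == "ar") ar_features(x, ar_order)$vector else band_power_features(x)$vector
    p <- forward(network, vec)
    times <- c(times, t_end)
    probs <- c(probs, p[["braking"]])
    if (p[["braking"]] > p[["normal"]]) {
      run <- run + 1
      if (run == smoothing_n) det_times <- c(det_times, t_end)
    } else {
      run <- 0
    }
    if (next_sample + step_n > n) break
    # slide: append step_n new samples, drop the oldest
    new_idx <- (next_sample + 1):(next_sample + step_n)
    buffer <- cbind(buffer[, -seq_len(step_n), drop = FALSE],
                    session$eeg[, new_idx, drop = FALSE])
    next_sample <- next_sample + step_n
  }

  events <- detect_braking_events(session, step_ms = step_ms)$event_time_s
  detections <- tibble::tibble(
    detection_time_s = det_times,
    event_time_s = NA_real_, lead_time_ms = NA_real_
  )
  if (nrow(detections) > 0 && length(events) > 0) {
    for (i in seq_len(nrow(detections))) {
      dt <- detections$detection_time_s[i]
      ahead <- events[events >= dt - 0.5 & events <= dt + 1.5]
      if (length(ahead) > 0) {
        detections$event_time_s[i] <- ahead[1]
        detections$lead_time_ms[i] <- (ahead[1] - dt) * 1000
      }
    }
  }
  structure(
    list(
      predictions = tibble::tibble(
        time_s = times,
        .pred_class = factor(ifelse(probs > 0.5, "braking", "normal"),
                             levels = c("normal", "braking")),
        .pred_braking = probs
      ),
      detections = detections,
      step_ms = step_ms,
      smoothing_n = smoothing_n,
      events = events
    ),
    class = "brake_stream"
  )
}

#' @export
print.brake_stream <- function(x, ...) {
  cat(sprintf(
    "<brake_stream> %d predictions every %g ms | %d detections (%d matched to events)\n",
    nrow(x$predictions), x$step_ms, nrow(x$detections),
    sum(!is.na(x$detections$event_time_s))
  ))
  invisible(x)
}

#' Score a streaming run against ground truth
#'
#' Per-step accuracy uses the same labeling rules as training: steps ending
#' inside a pre-braking window count as braking, steps in the 5-s post-event
#' discard zone are excluded, remaining steps at least 5 s from every event
#' are normal. Event recall is the fraction of events with at least one
#' braking prediction (or detection, when `stream` is a `brake_stream`)
#' inside their pre-braking window; lead times are averaged over matched
#' detections.
#'
#' @param stream A `brake_stream`, or a predictions tibble (`time_s`,
#'   `.pred_class`).
#' @param truth_events Event times (numeric) or a `truth_events` tibble.
#' @param pre_braking_ms Pre-braking period used for step labels and recall.
#' @param config A [labeling_config()] for discard/quiet margins.
#' @return One-row tibble: `step_accuracy`, `event_recall`,
#'   `mean_lead_time_ms`, `false_alarms`, `n_steps_scored`, `n_events`.
#'   Event metrics are `NA` when the session has no events.
#' @export
evaluate_online <- function(stream, truth_events, pre_braking_ms = 1000,
                            config = labeling_config(pre_braking_ms = pre_braking_ms)) {
  preds <- if (inherits(stream, "brake_stream")) stream$predictions else stream
  if (is.data.frame(truth_events)) truth_events <- truth_events$braking_time_s
  events <- sort(truth_events)
  p_s <- pre_braking_ms / 1000
  t <- preds$time_s

  tol <- 1e-6
  true_label <- rep("normal", length(t))
  scored <- rep(TRUE, length(t))
  for (e in events) {
    in_pre <- t - (e - p_s) > tol & t <= e + tol
    true_label[in_pre] <- "braking"
    in_discard <- t > e + tol & t - 1 < e + config$discard_after_s
    scored[in_discard] <- FALSE
    near <- abs(t - e) < config$min_event_separation_s & true_label == "normal"
    scored[near & !in_pre] <- FALSE
  }
  step_acc <- if (any(scored)) {
    mean(true_label[scored] == as.character(preds$.pred_class[scored]))
  } else {
    NA_real_
  }

  if (length(events) == 0) {
    return(tibble::tibble(step_accuracy = step_acc, event_recall = NA_real_,
                          mean_lead_time_ms = NA_real_, false_alarms = NA_integer_,
                          n_steps_scored = sum(scored), n_events = 0L))
  }
  hit_times <- if (inherits(stream, "brake_stream")) {
    stream$detections$detection_time_s
  } else {
    t[preds$.pred_class == "braking"]
  }
  recalled <- vapply(events, function(e) {
    any(hit_times - (e - p_s) > 1e-6 & hit_times <= e + 1e-6)
  }, logical(1))
  lead <- if (inherits(stream, "brake_stream")) {
    stream$detections$lead_time_ms[!is.na(stream$detections$lead_time_ms)]
  } else {
    unlist(lapply(events, function(e) {
      h <- hit_times[hit_times - (e - p_s) > 1e-6 & hit_times <= e + 1e-6]
      if (length(h)) (e - h[1]) * 1000 else numeric(0)
    }))
  }
  fa <- sum(vapply(hit_times, function(h) {
    all(h < events - p_s - 0.5 | h > events + config$discard_after_s)
  }, logical(1)))
  tibble::tibble(
    step_accuracy = step_acc,
    event_recall = mean(recalled),
    mean_lead_time_ms = if (length(lead)) mean(lead) else NA_real_,
    false_alarms = as.integer(fa),
    n_steps_scored = sum(scored),
    n_events = length(events)
  )
}
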