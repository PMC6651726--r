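#' Build a labeled feature dataset from labeled windows
#'
#' Runs the preprocessing chain (band-pass, optional ICA + approximate-entropy
#' artifact removal) and one feature extractor on every labeled window, and
#' assembles the result as one tibble: `label`, window provenance, then one
#' column per feature dimension (`F3_delta`..`O2_gamma` for band power,
#' `F3_ar_1`..`O2_nvar` for the AR family). Metadata (feature kind, AR order,
#' step and pre-braking period) travels in attributes so the model layer can
#' check input sizes.
#'
#' @param labeled Tibble from [label_windows()] (must carry `samples`,
#'   `label`, `end_time_s`).
#' @param feature `"ar"` or `"bandpower"`.
#' @param ar_order AR model order when `feature = "ar"`.
#' @param fs Sampling rate (Hz).
#' @param use_ica Run ICA artifact cleaning per window (default TRUE, as in
#'   the training flowchart).
#' @param apen_threshold Approximate-entropy threshold for artifact removal.
#' @param step_ms,pre_braking_ms Recorded as metadata.
#' @param seed Base seed for per-window ICA initialization.
#' @return A `brake_dataset` tibble: `label`, `window_end_s`,
#'   `source_event_s`, and D feature columns (D = 40 for band power,
#'   8 * (order + 1) for AR).
#' @export
featurize_windows <- function(labeled, feature = c("ar", "bandpower"),
                              ar_order = 10, fs = 128, use_ica = TRUE,
                              apen_threshold = 0.35, step_ms = NA_real_,
                              pre_braking_ms = NA_real_, seed = 1L) {
  feature <- match.arg(feature)
  stopifnot(is.data.frame(labeled), nrow(labeled) > 0,
            all(c("samples", "label", "end_time_s") %in% names(labeled)))
  feats <- purrr::map(seq_len(nrow(labeled)), function(i) {
    x <- preprocess_window(labeled$samples[[i]], fs = fs,
                           start_time_s = labeled$start_time_s[i],
                           use_ica = use_ica, apen_threshold = apen_threshold,
                           seed = seed)
    if (feature == "ar") ar_features(x, ar_order)$vector
    else band_power_features(x)$vector
  })
  fmat <- do.call(rbind, feats)
  out <- dplyr::bind_cols(
    tibble::tibble(
      label = labeled$label,
      window_end_s = labeled$end_time_s,
      source_event_s = if ("source_event_s" %in% names(labeled)) {
        labeled$source_event_s
      } else {
        NA_real_
      }
    ),
    tibble::as_tibble(fmat)
  )
  new_brake_dataset(out, feature = feature,
                    ar_order = if (feature == "ar") ar_order else NA_integer_,
                    step_ms = step_ms, pre_braking_ms = pre_braking_ms)
}

new_brake_dataset <- function(tbl, feature, ar_order = NA_integer_,
                              step_ms = NA_real_, pre_braking_ms = NA_real_) {
  d <- length(feature_cols(tbl))
  expected <- if (feature == "bandpower") 40L else 8L * (as.integer(ar_order) + 1L)
  if (!is.na(expected) && d != expected) {
    stop(sprintf("dataset has %d feature columns but metadata implies %d", d, expected))
  }
  structure(
    tbl,
    feature = feature, ar_order = ar_order,
    step_ms = step_ms, pre_braking_ms = pre_braking_ms,
    class = c("brake_dataset", class(tbl))
  )
}

#' Names of the feature columns of a dataset
#' @param data A `brake_dataset` (or any tibble following its layout).
#' @return Character vector of feature column names, in model input order.
#' @export
feature_cols <- function(data) {
  setdiff(names(data), c("label", "window_end_s", "source_event_s",
                         "start_time_s", "end_time_s", "samples"))
}

#' Extract the numeric feature matrix of a dataset
#' @param data A `brake_dataset`.
#' @return M x D numeric matrix.
#' @export
feature_matrix <- function(data) {
  as.matrix(data[, feature_cols(data), drop = FALSE])
}

#' End-to-end dataset construction from a session
#'
#' Convenience wrapper chaining [segment_windows()], [detect_braking_events()],
#' [label_windows()] and [featurize_windows()] with one set of parameters —
#' the training-mode path of the system.
#'
#' @param session A `brake_session`.
#' @param step_ms Sliding-window step (ms).
#' @param feature,ar_order,use_ica,apen_threshold See [featurize_windows()].
#' @param config A [labeling_config()].
#' @param events Optional event times to use instead of IMU detection.
#' @param seed Seed for normal-class subsampling and ICA initialization.
#' @return A `brake_dataset`.
#' @export
build_dataset <- function(session, step_ms = 125, feature = "ar",
                          ar_order = 10, config = labeling_config(),
                          use_ica = TRUE, apen_threshold = 0.35,
                          events = NULL, seed = 1L) {
  windows <- segment_windows(session, step_ms = step_ms)
  if (is.null(events)) {
    events <- detect_braking_events(session, step_ms = step_ms, config = config)
  }
  labeled <- label_windows(windows, events, session = session,
                           config = config, seed = seed)
  if (nrow(labeled) == 0) stop("no labelable windows in session")
  featurize_windows(labeled, feature = feature, ar_order = ar_order,
                    fs = session$fs, use_ica = use_ica,
                    apen_threshold = apen_threshold, step_ms = step_ms,
                    pre_braking_ms = config$pre_braking_ms, seed = seed)
}

#' Write / read a feature dataset as plain text
#'
#' CSV body preceded by `#`-prefixed metadata lines (`feature`, `ar_order`,
#' `step_ms`, `pre_braking_ms`), so a dataset round-trips with its model-input
#' contract intact.
#'
#' @param data A `brake_dataset`.
#' @param path Output path (`.csv`).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()` a
#'   `brake_dataset`.
#' @export
write_dataset <- function(data, path) {
  meta <- sprintf("# %s: %s",
                  c("feature", "ar_order", "step_ms", "pre_braking_ms"),
                  c(attr(data, "feature"), attr(data, "ar_order"),
                    attr(data, "step_ms"), attr(data, "pre_braking_ms")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(data), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- stats::setNames(
    sub("^# [a-z_]+: ", "", meta_lines),
    sub("^# ([a-z_]+):.*$", "\\1", meta_lines)
  )
  body <- utils::read.csv(text = lines[!startsWith(lines, "# ")])
  body$label <- factor(body$label, levels = c("normal", "braking"))
  new_brake_dataset(
    tibble::as_tibble(body),
    feature = meta[["feature"]],
    ar_order = suppressWarnings(as.integer(meta[["ar_order"]])),
    step_ms = suppressWarnings(as.numeric(meta[["step_ms"]])),
    pre_braking_ms = suppressWarnings(as.numeric(meta[["pre_braking_ms"]]))
  )
}
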