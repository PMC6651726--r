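#' Labeling configuration
#'
#' Thresholds and timing rules for IMU-driven automatic labeling. The
#' standard-deviation thresholds follow the deployed system: 120 counts for
#' the gyroscope magnitude and 12 for the accelerometer magnitude within a
#' 1-s window. `pre_braking_ms` selects which window ends before an executed
#' braking event are labeled "braking intention"; samples within
#' `discard_after_s` after an event are dropped as unstable.
#'
#' @param gyro_sd_threshold Gyro-magnitude SD threshold (counts).
#' @param accel_sd_threshold Accel-magnitude SD threshold (counts).
#' @param pre_braking_ms Pre-braking period in ms; one of 200, 400, 600, 800,
#'   1000 in the standard sweeps, at most 1000.
#' @param discard_after_s Seconds after each event whose windows are discarded.
#' @param min_event_separation_s Positive IMU windows closer than this
#'   collapse into one event; normal windows must be at least this far from
#'   every event on both sides.
#' @param normal_max_ratio Normal-driving samples are subsampled (seeded) to
#'   at most this multiple of the braking-sample count, keeping class
#'   imbalance near the ~1.9:1 ratio the pipeline was designed for.
#' @return A validated list of class `labeling_config`.
#' @export
labeling_config <- function(gyro_sd_threshold = 120,
                            accel_sd_threshold = 12,
                            pre_braking_ms = 1000,
                            discard_after_s = 5,
                            min_event_separation_s = 5,
                            normal_max_ratio = 2) {
  stopifnot(
    gyro_sd_threshold > 0, accel_sd_threshold > 0,
    pre_braking_ms > 0, pre_braking_ms <= 1000,
    discard_after_s > 0, min_event_separation_s > 0, normal_max_ratio > 0
  )
  structure(
    list(gyro_sd_threshold = gyro_sd_threshold,
         accel_sd_threshold = accel_sd_threshold,
         pre_braking_ms = pre_braking_ms,
         discard_after_s = discard_after_s,
         min_event_separation_s = min_event_separation_s,
         normal_max_ratio = normal_max_ratio),
    class = "labeling_config"
  )
}

# within-window SD of the 3-axis vector magnitude, per sliding window start
imu_window_sd <- function(imu3, starts, win_n) {
  mag <- sqrt(colSums(imu3^2))
  vapply(starts, function(s0) stats::sd(mag[(s0 + 1):(s0 + win_n)]), numeric(1))
}

#' Detect executed braking events from the IMU stream
#'
#' Slides a 1-s window along the 6-channel IMU data; a window is
#' event-positive when the standard deviation of the gyro vector magnitude
#' exceeds `gyro_sd_threshold` OR that of the accelerometer magnitude exceeds
#' `accel_sd_threshold`. Runs of positive windows closer than
#' `min_event_separation_s` collapse into a single event, timestamped at the
#' end of the first positive window (the earliest step-grid time at which the
#' threshold crossing is visible).
#'
#' @param session A `brake_session` (or a 6 x N IMU matrix via `imu` +
#'   `fs` arguments).
#' @param step_ms Sliding step in ms.
#' @param config A [labeling_config()].
#' @param window_s Window length in seconds.
#' @return Tibble with one row per event: `event_time_s`, `first_window_start_s`,
#'   `gyro_sd`, `accel_sd` (values in the first positive window).
#' @export
detect_braking_events <- function(session, step_ms = 125,
                                  config = labeling_config(), window_s = 1) {
  if (inherits(session, "brake_session")) {
    imu <- session$imu
    fs <- session$fs
  } else {
    stop("`session` must be a brake_session; build one with new_session() or simulate_session()")
  }
  step_n <- as.integer(round(step_ms / 1000 * fs))
  win_n <- as.integer(round(window_s * fs))
  n <- ncol(imu)
  empty <- tibble::tibble(event_time_s = numeric(0), first_window_start_s = numeric(0),
                          gyro_sd = numeric(0), accel_sd = numeric(0))
  if (n < win_n) return(empty)
  starts <- seq.int(0L, n - win_n, by = step_n)
  accel_sd <- imu_window_sd(imu[1:3, , drop = FALSE], starts, win_n)
  gyro_sd <- imu_window_sd(imu[4:6, , drop = FALSE], starts, win_n)
  positive <- gyro_sd > config$gyro_sd_threshold | accel_sd > config$accel_sd_threshold
  if (!any(positive)) return(empty)
  pos_t <- (starts[positive] + win_n) / fs
  keep <- c(TRUE, diff(pos_t) >= config$min_event_separation_s)
  idx <- which(positive)[keep]
  tibble::tibble(
    event_time_s = (starts[idx] + win_n) / fs,
    first_window_start_s = starts[idx] / fs,
    gyro_sd = gyro_sd[idx],
    accel_sd = accel_sd[idx]
  )
}

#' Label analysis windows from detected braking events
#'
#' A window ending at time `t` is labeled `braking` when some event `e`
#' satisfies `t` in `(e - pre_braking_ms, e]` — so with a 1000-ms pre-braking
#' period and 125-ms steps every event contributes exactly 8 windows, the last
#' one ending at the event itself. Windows overlapping `(e, e + discard_after_s]`
#' are discarded. Windows are labeled `normal` only when their IMU magnitude
#' SD is below both thresholds and they end at least `min_event_separation_s`
#' from every event on both sides; normal windows are then subsampled (seeded)
#' to at most `normal_max_ratio` times the braking count.
#'
#' @param windows Tibble from [segment_windows()].
#' @param events Event times: numeric vector, or the tibble returned by
#'   [detect_braking_events()].
#' @param session The session the windows came from (for the IMU quiet check);
#'   pass `NULL` to skip that check.
#' @param config A [labeling_config()].
#' @param seed Seed for the normal-class subsampling.
#' @return The `windows` tibble restricted to labeled rows, with added
#'   columns `label` (factor normal/braking, normal first) and
#'   `source_event_s` (the matched event for braking rows, `NA` otherwise).
#' @export
label_windows <- function(windows, events, session = NULL,
                          config = labeling_config(), seed = 1L) {
  if (is.data.frame(events)) events <- events$event_time_s
  events <- sort(events)
  p_s <- config$pre_braking_ms / 1000
  ends <- windows$end_time_s

  source_event <- rep(NA_real_, length(ends))
  tol <- 1e-6 # well below any step size; keeps (e - P, e] strictly half-open
  for (e in events) {
    hit <- ends - (e - p_s) > tol & ends <= e + tol
    source_event[hit] <- e
  }
  is_braking <- !is.na(source_event)

  discarded <- rep(FALSE, length(ends))
  near_event <- rep(FALSE, length(ends))
  for (e in events) {
    # window overlaps (e, e + discard_after_s]
    discarded <- discarded |
      (windows$start_time_s < e + config$discard_after_s & ends > e + tol)
    near_event <- near_event |
      abs(ends - e) < config$min_event_separation_s
  }

  quiet <- rep(TRUE, length(ends))
  if (!is.null(session)) {
    fs <- session$fs
    win_n <- as.integer(round((ends[1] - windows$start_time_s[1]) * fs))
    starts_n <- as.integer(round(windows$start_time_s * fs))
    a_sd <- imu_window_sd(session$imu[1:3, , drop = FALSE], starts_n, win_n)
    g_sd <- imu_window_sd(session$imu[4:6, , drop = FALSE], starts_n, win_n)
    quiet <- a_sd <= config$accel_sd_threshold & g_sd <= config$gyro_sd_threshold
  }

  is_normal <- !is_braking & !discarded & !near_event & quiet
  keep_braking <- which(is_braking & !discarded)
  keep_normal <- which(is_normal)
  n_keep <- min(length(keep_normal),
                ceiling(config$normal_max_ratio * length(keep_braking)))
  if (length(keep_braking) > 0 && length(keep_normal) > n_keep) {
    keep_normal <- withr::with_seed(as.integer(seed),
                                    sort(sample(keep_normal, n_keep)))
  }

  out <- windows[sort(c(keep_braking, keep_normal)), , drop = FALSE]
  sel <- sort(c(keep_braking, keep_normal))
  out$label <- factor(ifelse(sel %in% keep_braking, "braking", "normal"),
                      levels = c("normal", "braking"))
  out$source_event_s <- source_event[sel]
  out
}
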