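#' Segment a session into sliding 1-s multichannel windows
#'
#' Windows are half-open `[start, start + window_s)` in sample terms: a window
#' starting at time `t` holds samples `t, t + 1/fs, ..., t + window_s - 1/fs`.
#' Consecutive starts differ by `step_ms`; a trailing partial window is
#' dropped. A session shorter than one window yields zero rows.
#'
#' @param session A `brake_session`.
#' @param window_s Analysis window length in seconds (default 1).
#' @param step_ms Step size in milliseconds. 62.5, 125 and 250 ms correspond
#'   to 8, 16 and 32 new samples per step at 128 Hz; any positive multiple of
#'   the sample period is accepted.
#' @return A tibble with one row per window: `start_time_s`, `end_time_s`
#'   (= start + window length), and `samples`, a list-column of 8 x L
#'   matrices (L = `window_s * fs`).
#' @export
segment_windows <- function(session, window_s = 1, step_ms = 125) {
  stopifnot(inherits(session, "brake_session"), step_ms > 0)
  fs <- session$fs
  step_n <- step_ms / 1000 * fs
  if (abs(step_n - round(step_n)) > 1e-9) {
    stop("`step_ms` must be a positive multiple of the sample period (1000/fs ms)")
  }
  step_n <- as.integer(round(step_n))
  win_n <- as.integer(round(window_s * fs))
  n <- ncol(session$eeg)
  if (n < win_n) {
    return(tibble::tibble(
      start_time_s = numeric(0), end_time_s = numeric(0), samples = list()
    ))
  }
  starts <- seq.int(0L, n - win_n, by = step_n)
  tibble::tibble(
    start_time_s = starts / fs,
    end_time_s = (starts + win_n) / fs,
    samples = lapply(starts, function(s0) session$eeg[, (s0 + 1):(s0 + win_n), drop = FALSE])
  )
}

#' Zero-phase band-pass filter for a multichannel window
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), so the
#' pass band covers the EEG rhythms of interest (1-60 Hz by default) with no
#' phase distortion inside the short analysis window.
#'
#' @param x An 8 x L numeric matrix (channels x samples), or any matrix whose
#'   rows are channels.
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Band edges; must satisfy 0 < low < high < fs/2.
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, fs = 128, low_hz = 1, high_hz = 60) {
  stopifnot(is.matrix(x), low_hz > 0, high_hz > low_hz)
  if (high_hz >= fs / 2) stop("`high_hz` must be below the Nyquist frequency fs/2")
  bf <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  # remove the channel mean first: the short window makes filtfilt edge
  # transients significant for a large DC offset
  out <- t(apply(x, 1, function(row) signal::filtfilt(bf, row - mean(row))))
  dimnames(out) <- dimnames(x)
  out
}

#' Approximate entropy of a univariate series
#'
#' ApEn(m, r) = Phi^m(r) - Phi^(m+1)(r), where Phi^m is the average natural
#' log of the fraction of length-m templates lying within Chebyshev distance
#' `r` of each template (self-matches included). Low values indicate regular,
#' predictable signals such as blink artifacts; broadband EEG scores high.
#' With `r` proportional to the series SD the statistic is amplitude-scale
#' invariant.
#'
#' @param x Numeric series, length >= m + 2.
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a fraction of `sd(x)` (default 0.2).
#' @return Non-negative scalar; 0 for a constant series by convention.
#' @export
approximate_entropy <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  stopifnot(n >= m + 2)
  r <- r_factor * stats::sd(x)
  if (!is.finite(r) || r == 0) return(0)
  d0 <- abs(outer(x, x, "-")) # shared base for both template lengths
  phi <- function(mm) {
    nt <- n - mm + 1
    d <- d0[1:nt, 1:nt]
    if (mm > 1) {
      for (k in 1:(mm - 1)) {
        d <- pmax(d, d0[(1 + k):(nt + k), (1 + k):(nt + k)])
      }
    }
    mean(log(rowSums(d <= r) / nt))
  }
  phi(m) - phi(m + 1)
}
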