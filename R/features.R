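#' Canonical EEG frequency bands (Hz)
#'
#' delta 1-4, theta 4-8, alpha 8-14, beta 14-30, gamma 30-60 Hz. Edges are
#' half-open `[low, high)` so adjacent bands never double-count a bin.
#' @return Named list of `c(low, high)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 14),
       beta = c(14, 30), gamma = c(30, 60))
}

#' Relative band-power feature of a window
#'
#' Each channel of the 1-s window is zero-padded to 512 points and Fourier
#' transformed, giving a 0.25-Hz frequency resolution at 128 Hz. Absolute band
#' power PB_i sums the periodogram bins whose frequency falls in band i
#' (half-open edges); relative power rPB_i = PB_i / sum_i PB_i, so the five
#' values per channel always sum to one. The flattened feature vector is
#' channel-major (F3 delta..gamma, F4 delta..gamma, ...), length 40.
#'
#' @param x 8 x L window matrix (L = 128 at 128 Hz).
#' @param fs Sampling rate (Hz).
#' @param n_fft FFT length after zero padding (default 512).
#' @param taper Apply a Hann taper before padding (default FALSE: plain
#'   periodogram of the zero-padded segment).
#' @return Object of class `band_power`: `absolute` and `relative` (5 x 8
#'   matrices, bands x channels) and `vector` (named length-40 numeric).
#'   An all-zero channel gets uniform rPB = 0.2 per band and is recorded in
#'   `flat_channels`.
#' @export
band_power_features <- function(x, fs = 128, n_fft = 512, taper = FALSE) {
  stopifnot(is.matrix(x), ncol(x) <= n_fft)
  bands <- eeg_bands()
  freqs <- (seq_len(n_fft) - 1) * fs / n_fft
  half <- freqs < fs / 2
  ch_names <- rownames(x)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nrow(x)))
  absolute <- matrix(0, length(bands), nrow(x),
                     dimnames = list(names(bands), ch_names))
  flat <- logical(nrow(x))
  for (ch in seq_len(nrow(x))) {
    seg <- x[ch, ]
    if (taper) seg <- seg * (0.5 - 0.5 * cos(2 * pi * seq_along(seg) / (length(seg) + 1)))
    padded <- c(seg, numeric(n_fft - length(seg)))
    psd <- Mod(stats::fft(padded))^2 / length(seg)
    for (b in seq_along(bands)) {
      sel <- half & freqs >= bands[[b]][1] & freqs < bands[[b]][2]
      absolute[b, ch] <- sum(psd[sel])
    }
    flat[ch] <- sum(absolute[, ch]) == 0
  }
  relative <- apply(absolute, 2, function(pb) {
    if (sum(pb) == 0) rep(1 / length(pb), length(pb)) else pb / sum(pb)
  })
  dimnames(relative) <- dimnames(absolute)
  vec <- as.numeric(relative)
  names(vec) <- paste(rep(ch_names, each = length(bands)),
                      rep(names(bands), times = length(ch_names)), sep = "_")
  structure(
    list(absolute = absolute, relative = relative, vector = vec,
         flat_channels = which(flat)),
    class = "band_power"
  )
}

#' Burg autoregressive fit of a univariate series
#'
#' Fits `x_t = sum_{i=1..p} phi_i x_{t-i} + e_t` (series mean-centered first,
#' with the mean recorded as the model constant) by the Burg recursion:
#' at each order the reflection coefficient minimizing the summed forward and
#' backward prediction-error power is computed and the coefficient vector is
#' updated through the Levinson recursion. Reflection coefficients satisfy
#' |k| <= 1, so the fitted model is stationary. Burg estimates are reliable on
#' segments as short as one second of EEG, which is why this estimator backs
#' the AR feature family.
#'
#' @param x Numeric series, length >= 2 * order.
#' @param order Model order p (3-20 in the supported sweeps).
#' @return List: `order`, `phi` (length p), `noise_variance`, `intercept`
#'   (the series mean; not part of the downstream feature), `reflection`.
#' @export
burg_ar <- function(x, order) {
  n <- length(x)
  stopifnot(order >= 1)
  if (n < 2 * order) stop("series too short: need length >= 2 * order")
  mu <- mean(x)
  x <- x - mu
  if (stats::var(x) == 0) stop("zero-variance series: AR fit undefined")
  f <- x # forward prediction errors
  b <- x # backward prediction errors
  a <- 1
  e <- sum(x^2) / n
  refl <- numeric(order)
  for (k in seq_len(order)) {
    fk <- f[(k + 1):n]
    bk <- b[k:(n - 1)]
    denom <- sum(fk^2) + sum(bk^2)
    if (denom == 0) {
      refl[k:order] <- 0
      a <- c(a, numeric(order - k + 1))
      break
    }
    kk <- -2 * sum(fk * bk) / denom
    refl[k] <- kk
    a <- c(a, 0) + kk * rev(c(a, 0))
    e <- e * (1 - kk^2)
    # errors at stage k are defined for t = k+1..n
    f_new <- fk + kk * bk
    b_new <- bk + kk * fk
    f <- c(numeric(k), f_new)
    b <- c(numeric(k), b_new)
  }
  list(order = order, phi = -a[-1], noise_variance = e,
       intercept = mu, reflection = refl)
}

#' Autoregressive feature of a window
#'
#' Runs [burg_ar()] on every channel and concatenates, in fixed montage order
#' (F3, F4, C3, C4, P3, P4, O1, O2), each channel's p coefficients followed
#' by its innovation variance — `order + 1` values per channel, matching the
#' classifier input sizes 32, 40, ..., 168 for orders 3 through 20. The
#' coefficients are invariant to amplitude scaling of the window; the
#' variance term carries the residual power the normalized coefficients
#' cannot. The window mean (the model constant) is recorded but excluded.
#'
#' @param x 8 x L window matrix.
#' @param order AR model order (default 10).
#' @return Object of class `ar_fit`: `order`, `coefficients` (order x 8
#'   matrix), `noise_variance` and `intercept` (length 8), `vector`
#'   (named length `8 * (order + 1)`).
#' @export
ar_features <- function(x, order = 10) {
  stopifnot(is.matrix(x))
  ch_names <- rownames(x)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nrow(x)))
  fits <- lapply(seq_len(nrow(x)), function(ch) {
    tryCatch(burg_ar(x[ch, ], order),
             error = function(e) stop(sprintf("channel %s: %s", ch_names[ch],
                                              conditionMessage(e)), call. = FALSE))
  })
  coefs <- vapply(fits, function(f) f$phi, numeric(order))
  coefs <- matrix(coefs, nrow = order, dimnames = list(NULL, ch_names))
  nvar <- vapply(fits, `[[`, numeric(1), "noise_variance")
  vec <- as.numeric(rbind(coefs, nvar))
  names(vec) <- paste(rep(ch_names, each = order + 1),
                      rep(c(paste0("ar_", seq_len(order)), "nvar"),
                          times = length(ch_names)), sep = "_")
  structure(
    list(order = order,
         coefficients = coefs,
         noise_variance = nvar,
         intercept = vapply(fits, `[[`, numeric(1), "intercept"),
         vector = vec),
    class = "ar_fit"
  )
}
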