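#' Infomax independent component analysis of one analysis window
#'
#' Extended-infomax ICA on an 8 x L window: the data are mean-centered and
#' whitened by PCA, then the unmixing matrix is estimated by natural-gradient
#' ascent of the infomax objective with the extended rule, which switches the
#' nonlinearity per component between super- and sub-Gaussian based on a
#' running kurtosis sign estimate. The decomposition satisfies
#' `components = unmixing %*% x` exactly, and `mixing` inverts `unmixing`, so
#' zeroing no component reconstructs the input to numerical precision.
#'
#' @param x 8 x L numeric matrix (a band-passed window).
#' @param seed Integer seed for the random rotation initializing the search;
#'   the same window and seed give an identical decomposition.
#' @param max_iter Maximum natural-gradient iterations (default 500).
#' @param tol Convergence tolerance on the unmixing-matrix update norm.
#' @return List of class `ica_result`: `unmixing` (W, 8 x 8), `mixing`
#'   (W^-1), `components` (Y = W x, 8 x L), `center` (per-channel means),
#'   `n_iter`, `converged`.
#' @export
infomax_ica <- function(x, seed = 1L, max_iter = 500, tol = 1e-7) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  nc <- nrow(x)
  L <- ncol(x)
  center <- rowMeans(x)
  xc <- x - center

  cv <- tcrossprod(xc) / L
  eig <- eigen(cv, symmetric = TRUE)
  rank_tol <- max(eig$values) * 1e-10
  if (any(eig$values < rank_tol)) {
    warning("window is (near) rank-deficient; whitening regularized")
    eig$values <- pmax(eig$values, rank_tol)
  }
  sphere <- eig$vectors %*% diag(1 / sqrt(eig$values)) %*% t(eig$vectors)
  xw <- sphere %*% xc

  withr::with_seed(as.integer(seed), {
    q <- qr.Q(qr(matrix(stats::rnorm(nc * nc), nc)))
  })
  W <- q
  lrate <- 0.05
  signs <- rep(1, nc) # +1 super-Gaussian, -1 sub-Gaussian
  I <- diag(nc)
  converged <- FALSE
  it <- 0
  prev_delta <- Inf
  while (it < max_iter) {
    it <- it + 1
    y <- W %*% xw
    # extended infomax natural gradient:
    #   dW = (I - K tanh(y) y^T / L - y y^T / L) W,  K = diag(signs)
    ty <- tanh(y)
    dW <- (I - (signs * ty) %*% t(y) / L - tcrossprod(y) / L) %*% W
    delta <- sqrt(sum(dW^2))
    if (!is.finite(delta)) stop("infomax diverged; inspect the input window")
    # anneal when the update grows, creep up while it shrinks
    if (delta > 1.5 * prev_delta) lrate <- lrate * 0.5 else lrate <- min(lrate * 1.02, 0.2)
    prev_delta <- delta
    W <- W + lrate * dW
    # kurtosis-sign update for the extended rule
    k <- rowMeans(y^4) / rowMeans(y^2)^2 - 3
    signs <- ifelse(k >= 0, 1, -1)
    if (delta * lrate < tol) {
      converged <- TRUE
      break
    }
  }

  unmixing <- W %*% sphere
  mixing <- solve(W) # sphere^-1 %*% W^-1 folded below
  mixing <- eig$vectors %*% diag(sqrt(eig$values)) %*% t(eig$vectors) %*% mixing
  structure(
    list(
      unmixing = unmixing,
      mixing = mixing,
      components = unmixing %*% xc,
      center = center,
      n_iter = it,
      converged = converged
    ),
    class = "ica_result"
  )
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf(
    "<ica_result> %d components, %d samples | %d iterations (%s)\n",
    nrow(x$components), ncol(x$components), x$n_iter,
    if (x$converged) "converged" else "max_iter reached"
  ))
  invisible(x)
}

#' Remove low-complexity artifact components from a window
#'
#' Motion and blink artifacts are large, smooth and repetitive, so their
#' independent components score low approximate entropy. Components with
#' ApEn below `apen_threshold` are zeroed and the window is rebuilt through
#' the mixing matrix. If every component falls below the threshold the input
#' is returned unchanged with a warning (all-zero EEG is never produced).
#'
#' @param x The 8 x L window `icares` was computed on.
#' @param icares An [infomax_ica()] result for `x`.
#' @param apen_threshold Components with approximate entropy below this are
#'   treated as artifacts. The default 0.35 sits near the 1st percentile of
#'   ApEn over clean simulated EEG components, far above blink-like bursts
#'   (ApEn < 0.1). 0 disables removal.
#' @param m,r_factor Passed to [approximate_entropy()].
#' @return List: `cleaned` (8 x L matrix), `removed` (indices of zeroed
#'   components), `apen` (per-component entropies).
#' @export
remove_artifact_components <- function(x, icares, apen_threshold = 0.35,
                                       m = 2, r_factor = 0.2) {
  stopifnot(inherits(icares, "ica_result"),
            ncol(x) == ncol(icares$components))
  apen <- apply(icares$components, 1, approximate_entropy,
                m = m, r_factor = r_factor)
  flagged <- which(apen < apen_threshold)
  if (length(flagged) == nrow(icares$components)) {
    warning("all components fell below the ApEn threshold; window returned unfiltered")
    return(list(cleaned = x, removed = integer(0), apen = apen))
  }
  if (length(flagged) == 0) {
    return(list(cleaned = x, removed = integer(0), apen = apen))
  }
  comps <- icares$components
  comps[flagged, ] <- 0
  cleaned <- icares$mixing %*% comps + icares$center
  dimnames(cleaned) <- dimnames(x)
  list(cleaned = cleaned, removed = flagged, apen = apen)
}

#' Preprocess one window: band-pass then optional ICA artifact cleaning
#'
#' The per-window ICA seed is derived from the window's start sample so that
#' streaming and batch analysis of the same session produce bit-identical
#' results regardless of call order.
#'
#' @param x 8 x L window matrix.
#' @param fs Sampling rate (Hz).
#' @param start_time_s Window start time, used to derive the ICA seed.
#' @param use_ica Run ICA + ApEn artifact removal after filtering.
#' @param apen_threshold See [remove_artifact_components()].
#' @param low_hz,high_hz Band edges for [bandpass_filter()].
#' @param seed Base seed for the per-window ICA initialization.
#' @return Preprocessed 8 x L matrix.
#' @export
preprocess_window <- function(x, fs = 128, start_time_s = 0, use_ica = TRUE,
                              apen_threshold = 0.35, low_hz = 1, high_hz = 60,
                              seed = 1L) {
  out <- bandpass_filter(x, fs = fs, low_hz = low_hz, high_hz = high_hz)
  if (use_ica) {
    wseed <- (as.integer(seed) + round(start_time_s * fs)) %% .Machine$integer.max
    ic <- infomax_ica(out, seed = wseed)
    out <- remove_artifact_components(out, ic, apen_threshold)$cleaned
  }
  out
}
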