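test_that("window segmentation follows the sliding-step grid", {
  sess10 <- cached_session("seg10", duration_s = 10, seed = 4)
  w <- segment_windows(sess10, step_ms = 125)
  # floor((10 - 1) / 0.125) + 1 starts, from 0.0 to 9.0 s
  expect_equal(nrow(w), 73)
  expect_equal(w$start_time_s[1], 0)
  expect_equal(w$start_time_s[73], 9)
  expect_true(all(abs(diff(w$start_time_s) - 0.125) < 1e-12))
  expect_true(all(vapply(w$samples, ncol, integer(1)) == 128L))
  expect_true(all(vapply(w$samples, nrow, integer(1)) == 8L))
  # 125 ms at 128 Hz = 16 new samples per step
  expect_equal(diff(w$start_time_s)[1] * sess10$fs, 16)

  short <- new_session(matrix(rnorm(8 * 64), 8), matrix(0, 6, 64))
  expect_equal(nrow(segment_windows(short, step_ms = 125)), 0)

  expect_error(segment_windows(sess10, step_ms = 100.3), "multiple")
})

test_that("band-pass keeps in-band tones and suppresses DC", {
  t <- (0:127) / 128
  tone <- matrix(sin(2 * pi * 10 * t), 1)
  out <- bandpass_filter(tone, 128)
  expect_gt(max(abs(out[1, 30:98])), 0.9)
  expect_lt(max(abs(out[1, 30:98])), 1.1)

  expect_lt(max(abs(bandpass_filter(matrix(1, 1, 128), 128))), 0.1)
  expect_equal(bandpass_filter(matrix(0, 2, 128), 128), matrix(0, 2, 128))
  expect_error(bandpass_filter(tone, 128, high_hz = 64), "Nyquist")
})

test_that("approximate entropy matches brute-force template counting", {
  withr::with_seed(42, {
    for (n in c(10, 25, 50)) {
      x <- rnorm(n)
      expect_equal(approximate_entropy(x), apen_bruteforce(x), tolerance = 1e-12)
    }
    x <- sample(c(0.1, 0.2, 0.3), 30, replace = TRUE) # heavy ties
    expect_equal(approximate_entropy(x), apen_bruteforce(x), tolerance = 1e-12)
  })
})

test_that("approximate entropy orders signals by regularity and scales freely", {
  expect_identical(approximate_entropy(rep(3, 20)), 0)
  withr::with_seed(1, {
    noise <- rnorm(50)
    alt <- rep(c(1, -1), 25)
    expect_lt(approximate_entropy(alt), approximate_entropy(noise))
    # r proportional to SD makes ApEn amplitude-invariant
    expect_equal(approximate_entropy(noise), approximate_entropy(57.3 * noise),
                 tolerance = 1e-12)
  })
})

test_that("infomax ICA recovers planted super-Gaussian sources", {
  withr::with_seed(1, {
    s <- matrix(rt(2 * 512, df = 3), 2)
    mixing <- matrix(rnorm(16), 8, 2)
    x <- mixing %*% s + 0.1 * matrix(rnorm(8 * 512), 8)
  })
  ic <- infomax_ica(x, seed = 2, max_iter = 1000)
  cors <- abs(stats::cor(t(ic$components), t(s)))
  expect_gt(max(cors[, 1]), 0.9)
  expect_gt(max(cors[, 2]), 0.9)
})

test_that("ICA reconstruction and determinism invariants hold", {
  sess <- fixture_session()
  x <- bandpass_filter(sess$eeg[, 1:128], sess$fs)
  ic <- infomax_ica(x, seed = 3)
  # Y = W (x - center) exactly, and mixing inverts unmixing
  expect_equal(ic$components, ic$unmixing %*% (x - rowMeans(x)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ic$mixing %*% ic$components + ic$center, x,
               tolerance = 1e-8, ignore_attr = TRUE)
  ic2 <- infomax_ica(x, seed = 3)
  expect_identical(ic$unmixing, ic2$unmixing)

  rankdef <- matrix(1, 8, 1) %*% rnorm(128)
  expect_warning(infomax_ica(rankdef, seed = 1, max_iter = 5), "rank")
})

test_that("blink-like components are flagged and removed, clean EEG passes through", {
  sess <- fixture_session()
  clean <- bandpass_filter(sess$eeg[, 1:128], sess$fs)
  ic_clean <- infomax_ica(clean, seed = 5)
  blink <- 0.5 * (1 - cos(2 * pi * seq_len(128) / 129)) # smooth, low ApEn

  # the blink arrives along one source direction: zero that component in the
  # reference window, then inject the blink there, so the decomposition of
  # the contaminated window carries the artifact in exactly one component
  shares <- apply(ic_clean$components, 1, stats::sd)
  k <- which.min(shares)
  amp <- 30 * max(shares)
  comps_ref <- ic_clean$components
  comps_ref[k, ] <- 0
  clean_ref <- ic_clean$mixing %*% comps_ref + ic_clean$center
  contaminated <- clean_ref + ic_clean$mixing[, k, drop = FALSE] %*% t(amp * blink)
  ic <- list(
    unmixing = ic_clean$unmixing,
    mixing = ic_clean$mixing,
    components = ic_clean$unmixing %*% (contaminated - rowMeans(contaminated)),
    center = rowMeans(contaminated), n_iter = ic_clean$n_iter, converged = TRUE
  )
  class(ic) <- "ica_result"
  res <- remove_artifact_components(contaminated, ic, apen_threshold = 0.35)
  expect_true(k %in% res$removed)
  for (ch in 1:8) {
    expect_gt(stats::cor(res$cleaned[ch, ], clean_ref[ch, ]), 0.9)
  }

  # threshold 0 flags nothing: output is the input
  res0 <- remove_artifact_components(clean, ic_clean, 0)
  expect_identical(res0$cleaned, clean)
  expect_length(res0$removed, 0)

  # absurd threshold flags everything: refuse, warn, return input
  expect_warning(
    resall <- remove_artifact_components(clean, ic_clean, 1e6),
    "all components"
  )
  expect_identical(resall$cleaned, clean)
})

test_that("the full preprocessing chain is idempotent when nothing is removed", {
  sess <- fixture_session()
  w <- segment_windows(sess, step_ms = 250)
  x <- bandpass_filter(w$samples[[5]], sess$fs)
  ic <- infomax_ica(x, seed = 9)
  rebuilt <- remove_artifact_components(x, ic, apen_threshold = 0)$cleaned
  expect_lt(max(abs(rebuilt - x)), 1e-6 * sd(x))
})
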