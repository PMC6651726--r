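test_that("the 512-point periodogram yields 0.25-Hz bins and Eq-consistent powers", {
  t <- (0:127) / 128
  x <- matrix(0, 8, 128, dimnames = list(c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"), NULL))
  x[1, ] <- sin(2 * pi * 10 * t)
  x[2:8, ] <- rnorm(7 * 128)
  bp <- band_power_features(x, fs = 128, n_fft = 512)
  # frequency resolution 128/512 = 0.25 Hz: a 10.25 Hz tone falls on a bin
  expect_equal(128 / 512, 0.25)
  expect_gt(bp$relative["alpha", "F3"], 0.95)
  expect_equal(unname(colSums(bp$relative)), rep(1, 8), tolerance = 1e-9)
  expect_true(all(bp$relative >= 0 & bp$relative <= 1))
  expect_length(bp$vector, 40)
  expect_identical(names(bp$vector)[1:5],
                   c("F3_delta", "F3_theta", "F3_alpha", "F3_beta", "F3_gamma"))
})

test_that("an all-zero channel falls back to uniform relative power", {
  x <- matrix(rnorm(8 * 128), 8)
  x[3, ] <- 0
  bp <- band_power_features(x)
  expect_equal(unname(bp$relative[, 3]), rep(0.2, 5))
  expect_identical(bp$flat_channels, 3L)
})

test_that("band powers are stable under circular time shift", {
  # a tone periodic in the window is the clean stationary case: its band
  # profile must survive a circular shift within spectral-leakage tolerance
  t <- (0:127) / 128
  x <- matrix(rep(sin(2 * pi * 10 * t), 8), nrow = 8, byrow = TRUE) +
    0.05 * matrix(sin(2 * pi * 3 * t), 8, 128, byrow = TRUE)
  shifted <- x[, c(33:128, 1:32)]
  a <- band_power_features(x)$vector
  b <- band_power_features(shifted)$vector
  expect_lt(max(abs(a - b)), 0.05)
})

test_that("Burg matches the reference recursion and long-sample truth", {
  withr::with_seed(10, {
    x <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), 4096))
  })
  fit <- burg_ar(x, 2)
  # long-sample consistency against the generating coefficients
  expect_lt(max(abs(fit$phi - c(0.5, -0.3))), 0.05)
  # agreement with the stats implementation of the same recursion
  ref <- stats::ar.burg(x, aic = FALSE, order.max = 2, demean = TRUE)
  expect_equal(fit$phi, as.numeric(ref$ar), tolerance = 1e-10)
  # reflection coefficients bounded: the fit is stationary
  expect_true(all(abs(fit$reflection) <= 1))
  expect_true(all(Mod(polyroot(c(1, -fit$phi))) > 1))
})

test_that("white noise yields near-zero AR coefficients", {
  withr::with_seed(11, {
    phis <- replicate(50, max(abs(burg_ar(rnorm(128), 10)$phi)))
  })
  # null distribution: coefficients are O(1/sqrt(n)); allow the usual 3-sigma
  expect_gt(mean(phis < 3 / sqrt(128)), 0.8)
})

test_that("AR features scale correctly and reject degenerate input", {
  sess <- fixture_session()
  x <- sess$eeg[, 501:628]
  f1 <- burg_ar(x[1, ], 10)
  f2 <- burg_ar(5 * x[1, ], 10)
  expect_equal(f1$phi, f2$phi, tolerance = 1e-10)
  expect_equal(f2$noise_variance, 25 * f1$noise_variance, tolerance = 1e-8)

  expect_error(burg_ar(rnorm(16), 10), "too short")
  expect_error(burg_ar(rep(2, 128), 10), "zero-variance")
})

test_that("AR feature vectors have the documented length and layout", {
  sess <- fixture_session()
  x <- sess$eeg[, 101:228]
  expect_length(ar_features(x, 3)$vector, 32)
  expect_length(ar_features(x, 10)$vector, 88)
  expect_length(ar_features(x, 20)$vector, 168)
  af <- ar_features(x, 10)
  expect_identical(names(af$vector)[1:2], c("F3_ar_1", "F3_ar_2"))
  expect_identical(names(af$vector)[11:12], c("F3_nvar", "F4_ar_1"))

  # identical channels produce identical coefficient blocks
  same <- matrix(rep(x[1, ], 8), nrow = 8, byrow = TRUE)
  af2 <- ar_features(same, 5)
  expect_equal(af2$coefficients[, 1], af2$coefficients[, 8])

  # errors name the offending channel
  bad <- x
  bad[4, ] <- 7
  expect_error(ar_features(bad, 10), "channel C4")
})
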