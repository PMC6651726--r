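# a light model for streaming tests: trained on the shared fixture session
stream_model <- function() {
  if (is.null(.fixture_cache$stream_net)) {
    ds <- build_dataset(fixture_session(), step_ms = 250, feature = "ar",
                        ar_order = 6, config = labeling_config(pre_braking_ms = 600),
                        use_ica = FALSE, seed = 5)
    .fixture_cache$stream_net <- fit_mlp(ds, config = mlp_config(
      n_hidden = 20, max_iterations = 100, seed = 6
    ))
  }
  .fixture_cache$stream_net
}

test_that("the rolling buffer reproduces the batch prediction grid exactly", {
  sess <- cached_session("online40", duration_s = 40, seed = 31)
  net <- stream_model()
  st <- stream_detect(sess, net, step_ms = 250, feature = "ar", ar_order = 6,
                      use_ica = FALSE, seed = 5)
  # prediction count: floor((N - 128)/step) + 1
  n <- ncol(sess$eeg)
  expect_equal(nrow(st$predictions), floor((n - 128) / 32) + 1)
  expect_equal(st$predictions$time_s[1], 1)
  expect_true(all(abs(diff(st$predictions$time_s) - 0.25) < 1e-9))

  # batch path: same windows, same preprocessing seed, same model
  w <- segment_windows(sess, step_ms = 250)
  batch <- vapply(seq_len(nrow(w)), function(i) {
    x <- bandpass_filter(w$samples[[i]], sess$fs)
    forward(net, ar_features(x, 6)$vector)[["braking"]]
  }, numeric(1))
  expect_identical(st$predictions$.pred_braking, batch)
})

test_that("online and batch agree with ICA cleaning in the loop", {
  sess <- cached_session("online12", duration_s = 12, seed = 32)
  net <- stream_model()
  st <- stream_detect(sess, net, step_ms = 500, feature = "ar", ar_order = 6,
                      use_ica = TRUE, seed = 9)
  w <- segment_windows(sess, step_ms = 500)
  batch <- vapply(seq_len(nrow(w)), function(i) {
    x <- preprocess_window(w$samples[[i]], sess$fs,
                           start_time_s = w$start_time_s[i],
                           use_ica = TRUE, seed = 9)
    forward(net, ar_features(x, 6)$vector)[["braking"]]
  }, numeric(1))
  expect_identical(st$predictions$.pred_braking, batch)
})

test_that("step sizes respect the sample grid and buffer contract", {
  sess <- cached_session("online12", duration_s = 12, seed = 32)
  expect_error(stream_detect(sess, stream_model(), step_ms = 100.1), "multiple")
  # 62.5 ms -> 16 predictions per second of signal
  expect_equal(1000 / 62.5, 16)
})

test_that("trivial prediction streams score as expected", {
  events <- c(20, 50)
  t <- seq(1, 60, by = 0.25)
  all_normal <- tibble::tibble(
    time_s = t,
    .pred_class = factor(rep("normal", length(t)), levels = c("normal", "braking")),
    .pred_braking = rep(0.1, length(t))
  )
  m0 <- evaluate_online(all_normal, events, pre_braking_ms = 600)
  expect_equal(m0$event_recall, 0)

  # predictions copied from the true labels: perfect step accuracy and recall
  lab <- rep("normal", length(t))
  for (e in events) lab[t - (e - 0.6) > 1e-6 & t <= e + 1e-6] <- "braking"
  perfect <- tibble::tibble(
    time_s = t,
    .pred_class = factor(lab, levels = c("normal", "braking")),
    .pred_braking = as.numeric(lab == "braking")
  )
  m1 <- evaluate_online(perfect, events, pre_braking_ms = 600)
  expect_equal(m1$step_accuracy, 1)
  expect_equal(m1$event_recall, 1)

  # no events: event metrics are undefined-marked, not errors
  m2 <- evaluate_online(all_normal, numeric(0), pre_braking_ms = 600)
  expect_true(is.na(m2$event_recall))
  expect_equal(m2$n_events, 0L)
})

test_that("detections fire on braking events of a fresh session", {
  sess <- cached_session("online40", duration_s = 40, seed = 31)
  net <- stream_model()
  st <- stream_detect(sess, net, step_ms = 250, feature = "ar", ar_order = 6,
                      use_ica = FALSE, seed = 5)
  m <- evaluate_online(st, sess$truth_events, pre_braking_ms = 600)
  expect_gte(m$event_recall, 0.5)
  expect_gt(m$step_accuracy, 0.7)
})
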