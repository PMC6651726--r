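# Session fixtures are generated in code and memoised per test run, so the
# heavier pipeline tests can share one simulation.
.fixture_cache <- new.env(parent = emptyenv())

cached_session <- function(key, ...) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_session(sim_config(...))
  }
  .fixture_cache[[key]]
}

# 300-s default-condition session shared across labeling/pipeline tests
fixture_session <- function() cached_session("default300", duration_s = 300, seed = 101)

# independent brute-force ApEn oracle: direct template enumeration
apen_bruteforce <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  r <- r_factor * stats::sd(x)
  if (!is.finite(r) || r == 0) return(0)
  phi <- function(mm) {
    nt <- n - mm + 1
    counts <- vapply(seq_len(nt), function(i) {
      sum(vapply(seq_len(nt), function(j) {
        max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r
      }, logical(1)))
    }, numeric(1))
    mean(log(counts / nt))
  }
  phi(m) - phi(m + 1)
}

# independent AUC oracle: Mann-Whitney pair counting with ties = 1/2
auc_paircount <- function(y_true, scores) {
  pos <- scores[y_true == "braking"]
  neg <- scores[y_true == "normal"]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# two-Gaussian labeled dataset for classifier tests; gap 0 = pure noise
toy_dataset <- function(n_per_class = 60, d = 4, gap = 3, seed = 1) {
  withr::with_seed(seed, {
    xn <- matrix(rnorm(n_per_class * d), n_per_class)
    xb <- matrix(rnorm(n_per_class * d) + gap, n_per_class)
  })
  tbl <- tibble::tibble(
    label = factor(rep(c("normal", "braking"), each = n_per_class),
                   levels = c("normal", "braking")),
    window_end_s = seq_len(2 * n_per_class),
    source_event_s = NA_real_
  )
  feats <- tibble::as_tibble(as.data.frame(rbind(xn, xb)))
  names(feats) <- paste0("f", seq_len(d))
  dplyr::bind_cols(tbl, feats)
}
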