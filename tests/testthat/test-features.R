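test_that("time-domain statistics match hand-computed values", {
  f <- time_domain_features(c(1, 2, 3, 4))
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["sd"]], 1.290994, tolerance = 1e-6)
  expect_equal(f[["rms"]], 2.738613, tolerance = 1e-6)
  expect_equal(f[["iqr"]], 1.5)
  expect_equal(f[["cv"]], f[["sd"]] / 2.5)

  fc <- time_domain_features(rep(7, 100))
  expect_equal(unname(fc), c(7, 0, 0, 0, 7))

  # homogeneity: positive scaling scales the magnitude statistics, CV invariant
  set.seed(1)
  x <- rnorm(200, mean = 3)
  f1 <- time_domain_features(x)
  f3 <- time_domain_features(3 * x)
  expect_equal(f3[c("mean", "sd", "iqr", "rms")],
               3 * f1[c("mean", "sd", "iqr", "rms")])
  expect_equal(f3[["cv"]], f1[["cv"]])
  fm1 <- time_domain_features(-x)
  expect_equal(fm1[c("sd", "iqr", "rms")], f1[c("sd", "iqr", "rms")])
})

test_that("Welch PSD locates tones, is flat for noise, and conserves energy", {
  fs <- 50
  p <- welch_psd(make_sine(5, fs), fs)
  bin <- p$freq[2] - p$freq[1]
  expect_lt(abs(p$freq[which.max(p$psd)] - 5), bin + 1e-9)

  # flatness and Parseval on white noise, averaged over seeds
  set.seed(10)
  acc <- NULL
  ratio <- numeric(20)
  for (i in 1:20) {
    x <- rnorm(1500)
    pw <- welch_psd(x, fs)
    acc <- if (is.null(acc)) pw$psd else acc + pw$psd
    ratio[i] <- sum(pw$psd) * bin / var(x)
  }
  expect_lt(max(acc) / min(acc), 10)
  expect_lt(abs(mean(ratio) - 1), 0.05)

  expect_error(welch_psd(numeric(20), fs), "too short")
})

test_that("frequency features separate tones from noise", {
  fs <- 50
  fsine <- frequency_features(make_sine(5, fs), fs)
  expect_gte(fsine[["band_ratio"]], 0.9)
  expect_lte(fsine[["spec_entropy"]], 0.3)
  expect_lt(abs(fsine[["dom_freq"]] - 5), 0.2)

  set.seed(2)
  ent <- replicate(10, frequency_features(rnorm(1500), fs)[["spec_entropy"]])
  expect_gte(mean(ent), 0.9)

  # degenerate zero-power series maps to all zeros
  expect_equal(unname(frequency_features(numeric(1500), fs)), c(0, 0, 0))
})

test_that("approximate entropy equals the brute-force oracle exactly", {
  set.seed(5)
  corpus <- list(
    rnorm(60), rnorm(100), sin(2 * pi * 5 * (0:79) / 50),
    cumsum(rnorm(90)), runif(50), rep(c(0.1, 0.9, 0.4), 30),
    rnorm(70) + sin((1:70) / 3), round(rnorm(100), 1) # heavy ties
  )
  for (x in corpus) {
    expect_lt(abs(approximate_entropy(x) - apen_brute(x)), 1e-12)
  }
})

test_that("approximate entropy ranks irregularity and handles degenerate input", {
  expect_identical(approximate_entropy(rep(2, 100)), 0)
  expect_error(approximate_entropy(rnorm(10)), "too short")
  set.seed(6)
  ap_noise <- mean(replicate(20, approximate_entropy(rnorm(1500))))
  ap_sine <- mean(replicate(20, approximate_entropy(
    make_sine(5) + rnorm(1500, sd = 1e-3))))
  expect_gt(ap_noise, ap_sine)
})

test_that("autocorrelation zero crossing matches the quarter-period", {
  fs <- 50
  z <- autocorr_features(make_sine(5, fs), fs)[["acf_zero_lag"]]
  expect_gte(z, 0.05 - 1 / fs)
  expect_lte(z, 0.05 + 1 / fs)
  set.seed(7)
  lags <- replicate(20, autocorr_features(rnorm(1500), fs)[["acf_zero_lag"]])
  expect_lte(mean(lags), 3 / fs)
  expect_identical(autocorr_features(rep(1, 100), fs)[["acf_zero_lag"]], 0)
})

test_that("feature extraction yields the stable 90-column catalog", {
  w <- make_synthetic_window(1, seed = 3)
  fm <- extract_features(list(w, w, make_synthetic_window(0, seed = 4)))
  expect_identical(dim(fm$features), c(3L, 90L))
  expect_identical(colnames(fm$features), feature_names())
  expect_identical(fm$features[1, ], fm$features[2, ]) # duplicate window
  expect_identical(fm$labels, c(1L, 1L, 0L))
  expect_length(feature_names(), 90)
  expect_identical(anyDuplicated(feature_names()), 0L)
})

test_that("amplitude-doubling scales magnitude features and fixes shape features", {
  w <- make_synthetic_window(2, seed = 9)
  w2 <- w
  w2$data <- 2 * w$data
  f1 <- window_features(w)
  f2 <- window_features(w2)
  for (sfx in c("mean", "sd", "iqr", "rms")) {
    cols <- grep(paste0("__", sfx, "$"), names(f1))
    expect_equal(f2[cols], 2 * f1[cols], tolerance = 1e-8)
  }
  for (sfx in c("cv", "dom_freq", "band_ratio", "spec_entropy", "acf_zero_lag", "apen")) {
    cols <- grep(paste0("__", sfx, "$"), names(f1))
    expect_equal(f2[cols], f1[cols], tolerance = 1e-6)
  }
})
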