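test_that("session_config validates its invariants", {
  expect_s3_class(session_config(), "session_config")
  expect_error(session_config(severity_stationary = c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(session_config(tremor_amp = c(0.1, 0.5, 2)), "tremor_amp")
  expect_error(session_config(tremor_amp = c(0, 2, 0.5)), "tremor_amp")
  expect_error(session_config(fs = 12), "twice the upper tremor frequency")
  expect_error(session_config(nodata_prob = 1.5), "nodata_prob")
})

test_that("severity schedule hits the stationary occupancy", {
  # degenerate chain: all mass on severity 0
  cfg <- session_config(severity_stationary = c(1, 0, 0), duration_s = 3600)
  expect_true(all(severity_schedule(cfg)$severity == 0))

  # long-horizon occupancy within +/-0.01 of the stationary vector
  cfg <- session_config(duration_s = 1e6, seed = 11)
  sch <- severity_schedule(cfg)
  occ <- vapply(0:2, function(s)
    sum((sch$end_s - sch$start_s)[sch$severity == s]), 0) / 1e6
  expect_true(all(abs(occ - c(0.915, 0.075, 0.01)) < 0.01))

  # schedule tiles [0, duration] and is seed-reproducible
  expect_equal(sch$start_s[1], 0)
  expect_equal(tail(sch$end_s, 1), 1e6)
  expect_equal(sch$start_s[-1], head(sch$end_s, -1))
  expect_identical(sch, severity_schedule(cfg))
})

test_that("tremor component is a 4-7 Hz amplitude-modulated oscillation", {
  expect_equal(tremor_component(0, 30, 50, seed = 1), numeric(1500))
  x2 <- tremor_component(2, 60, 50, seed = 3)
  p <- welch_psd(x2, 50)
  expect_gte(p$freq[which.max(p$psd)], 4)
  expect_lte(p$freq[which.max(p$psd)], 7)
  # equal seeds share carrier and envelope, so RMS is monotone in amplitude
  x1 <- tremor_component(1, 60, 50, seed = 3)
  expect_gt(sqrt(mean(x2^2)), sqrt(mean(x1^2)))
})

test_that("voluntary component concentrates its power in 0.5-3 Hz", {
  v <- voluntary_component(120, 50, seed = 4)
  p <- welch_psd(v, 50)
  inband <- p$freq >= 0.5 & p$freq <= 3
  expect_gte(sum(p$psd[inband]) / sum(p$psd), 0.9)
  expect_lte(sum(p$psd[p$freq > 10]) / sum(p$psd), 0.01)
  expect_identical(voluntary_component(0, 50, seed = 1), numeric(0))
})

test_that("simulated sessions score on cadence with occupancy-modal labels", {
  cfg <- session_config(duration_s = 1800, nodata_prob = 0, seed = 21,
                        severity_stationary = c(0.5, 0.3, 0.2), mean_bout_s = 120)
  sim <- simulate_session(cfg)
  expect_equal(nrow(sim$events), floor(1800 / 180))
  expect_equal(nrow(sim$recording$acc), 1800 * 50)
  # every label equals the independently recomputed modal severity
  for (e in seq_len(nrow(sim$events))) {
    te <- sim$events$time_s[e]
    expect_identical(sim$events$label[e],
                     modal_label_oracle(sim$schedule, te - 30, te))
  }
  # NO_DATA saturation
  cfg_nd <- session_config(duration_s = 1800, nodata_prob = 1, seed = 22)
  expect_true(all(is.na(simulate_session(cfg_nd)$events$label)))
})

test_that("identical config and seed reproduce the session bit-for-bit", {
  cfg <- session_config(duration_s = 900, seed = 33)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$recording, s2$recording)
  expect_identical(s1$events, s2$events)
})

test_that("scored-label frequencies converge to the stationary vector", {
  cfg <- session_config(duration_s = 1.8e6 + 180, seed = 101)
  sch <- severity_schedule(cfg)
  times <- seq(180, 1.8e6, by = 180) # 10^4 scored intervals
  labs <- vapply(times, function(te) modal_label_oracle(sch, te - 30, te), 0L)
  freqs <- tabulate(labs + 1L, nbins = 3) / length(labs)
  expect_true(all(abs(freqs - c(0.915, 0.075, 0.01)) < 0.01))
})
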