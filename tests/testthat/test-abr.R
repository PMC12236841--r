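test_that("epoch averaging: identity, artifact cancellation, CLT noise scaling", {
  fs <- 25000
  e <- sin(2 * pi * 800 * seq(0, 0.008, by = 1 / fs))
  w <- average_epochs(cbind(e, e), fs = fs)
  expect_equal(w$samples, e)
  expect_equal(w$n_epochs_averaged, 2L)

  # pure artifact flips with polarity and cancels
  w2 <- average_epochs(cbind(e, -e), fs = fs, polarity = c(1, -1))
  expect_true(all(abs(w2$samples) < 1e-12))

  set.seed(5)
  n <- 1024
  epochs <- matrix(rnorm(200 * n), 200, n)
  w3 <- average_epochs(epochs, fs = fs)
  resid_rms <- sqrt(mean(w3$samples^2))
  expect_lt(abs(resid_rms - 1 / sqrt(n)) / (1 / sqrt(n)), 0.2)
  expect_error(average_epochs(matrix(1, 4, 1), fs), ">= 2")
})

test_that("alternating polarity suppresses a stimulus artifact by >= 40 dB", {
  ser <- simulate_abr_series(threshold_db = 200, noise_sigma_uv = 0,
                             artifact_uv = 5, seed = 1)
  w <- ser$waveforms[[1]]
  # the artifact is a narrow transient at t = 0; in the polarity-balanced
  # average it must be at least 100x (40 dB) below its single-epoch size
  expect_lt(max(abs(w$samples)), 5 / 100)
  # each split half is polarity-balanced too
  expect_lt(max(abs(w$half_a)), 5 / 100)
})

test_that("wave-1 metrics: planted peak/trough, zero waveform, global mode", {
  fs <- 25000
  t_ms <- seq(-1, 9, by = 1000 / fs)
  s <- 2 * exp(-0.5 * ((t_ms - 1.5) / 0.1)^2) -
    1 * exp(-0.5 * ((t_ms - 2.0) / 0.1)^2)
  w <- structure(list(samples = s, t_ms = t_ms, fs = fs), class = "abr_waveform")
  m <- wave1_metrics(w)
  expect_equal(m$amplitude_uv, 3, tolerance = 0.02)
  expect_equal(m$latency_ms, 1.5, tolerance = 0.05)

  w0 <- structure(list(samples = t_ms * 0, t_ms = t_ms, fs = fs),
                  class = "abr_waveform")
  expect_equal(wave1_metrics(w0)$amplitude_uv, 0)
  expect_gte(wave1_metrics(w)$amplitude_uv, 0)
  expect_error(wave1_metrics(w, window_ms = c(50, 60)), "no samples")
})

test_that("latency shifts exactly with a delayed template (shift equivariance)", {
  ser1 <- simulate_abr_series(threshold_db = 40, noise_sigma_uv = 0, seed = 1)
  tpl2 <- abr_template()
  tpl2$peaks$t_ms <- tpl2$peaks$t_ms + 0.4
  ser2 <- simulate_abr_series(threshold_db = 40, noise_sigma_uv = 0,
                              template = tpl2, seed = 1)
  w1 <- ser1$waveforms[[length(ser1$levels)]]
  w2 <- ser2$waveforms[[length(ser2$levels)]]
  l1 <- wave1_metrics(w1)$latency_ms
  l2 <- wave1_metrics(w2)$latency_ms
  expect_equal(l2 - l1, 0.4, tolerance = 1000 / w1$fs / 1000 + 1e-9)
})

test_that("simulated amplitudes track the planted template growth", {
  ser <- simulate_abr_series(threshold_db = 45, noise_sigma_uv = 0, seed = 2)
  w80 <- ser$waveforms[[which(ser$levels == 80)]]
  planted <- (0.5 + 0.15 * (80 - 45)) *
    cochleaquant:::template_p2p(abr_template())
  expect_equal(wave1_metrics(w80)$amplitude_uv, planted, tolerance = 0.1)
  # below threshold: silence
  w40 <- ser$waveforms[[which(ser$levels == 40)]]
  expect_equal(wave1_metrics(w40)$amplitude_uv, 0)
})

test_that("threshold detection: noise-free forced, all-noise censored", {
  ser <- simulate_abr_series(threshold_db = 45, noise_sigma_uv = 0, seed = 1)
  res <- detect_threshold(ser)
  expect_false(res$censored)
  expect_equal(res$threshold_db, 45)

  noise <- simulate_abr_series(threshold_db = 200, noise_sigma_uv = 0.5,
                               seed = 3)
  expect_true(detect_threshold(noise)$censored)
})

test_that("adding a response at a higher level never raises the threshold", {
  ser <- simulate_abr_series(threshold_db = 60, noise_sigma_uv = 0.3, seed = 8)
  base <- detect_threshold(ser)
  # replace the top level with a stronger response (threshold 55 grows more)
  ser2 <- ser
  strong <- simulate_abr_series(threshold_db = 55, noise_sigma_uv = 0.3,
                                seed = 9)
  ser2$waveforms[[length(ser2$levels)]] <-
    strong$waveforms[[length(strong$levels)]]
  res2 <- detect_threshold(ser2)
  expect_lte(res2$threshold_db, base$threshold_db)
})

test_that("threshold recovery holds across seeded noisy series", {
  ok <- 0
  for (s in 1:20) {
    ser <- simulate_abr_series(threshold_db = 45, noise_sigma_uv = 0.5,
                               seed = 400 + s)
    r <- detect_threshold(ser)
    if (!r$censored && abs(r$threshold_db - 45) <= 5) ok <- ok + 1
  }
  expect_gte(ok, 19)
})
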