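test_that("primary design follows the f2/f1 = 1.2, L2 = L1 - 10 rules exactly", {
  pp <- design_primaries(16000, 70)
  expect_equal(pp$f1, 16000 / 1.2)
  expect_equal(pp$L2, 60)
  expect_equal(pp$dp_frequency, 2 * 16000 / 1.2 - 16000)
  expect_equal(abs(pp$f2 / pp$f1 - 1.2), 0, tolerance = 1e-6)

  pp2 <- design_primaries(22650, 65)
  expect_equal(pp2$f1, 18875)
  expect_equal(pp2$dp_frequency, 15100)
  expect_equal(design_primaries(12000, 60)$dp_frequency, 8000)
  expect_error(design_primaries(-1, 60), "f2")
})

test_that("a planted DP measures back within 0.1 dB without noise", {
  rec <- simulate_ear_canal(12000, 60, dp_level = 30, noise_floor_db = NULL,
                            seed = 1)
  m <- measure_dp(rec)
  expect_equal(m$dp_level, 30, tolerance = 0.1)
  expect_gt(m$snr, 1)
})

test_that("calibration round-trip holds across levels (tones on analysis bins)", {
  for (X in c(0, 20, 40, 60, 80)) {
    rec <- simulate_ear_canal(12000, X, dp_level = NULL,
                              noise_floor_db = NULL, seed = 1)
    sp <- welch_amplitude_spectrum(rec$samples, rec$fs)
    b <- which.min(abs(sp$freq - 12000))
    expect_equal(20 * log10(sp$amp[b]), X - 10, tolerance = 0.1)
  }
})

test_that("Parseval: rectangular-window spectral power equals time-domain power", {
  fs <- 62500
  t <- (0:(fs / 2 - 1)) / fs
  x <- 0.7 * sin(2 * pi * 1000 * t) + 0.2 * sin(2 * pi * 5000 * t)
  cfg <- dp_spec_cfg(n_segments = 1, window = "rect")
  sp <- welch_amplitude_spectrum(x, fs, cfg)
  # one-sided amplitude spectrum: power = sum(amp^2)/2
  expect_equal(sum(sp$amp^2) / 2, mean(x^2), tolerance = 1e-3)
})

test_that("silence yields the numerical floor and SNR <= 1", {
  rec <- simulate_ear_canal(12000, -200, dp_level = NULL,
                            noise_floor_db = NULL, seed = 1)
  rec$samples <- rec$samples * 0
  m <- measure_dp(rec)
  expect_lte(m$snr, 1)
  expect_equal(m$noise_floor, 20 * log10(dp_spec_cfg()$amp_eps))
})

test_that("without an emission the SNR is not systematically above 1", {
  snrs <- vapply(1:15, function(s) {
    rec <- simulate_ear_canal(12000, 60, dp_level = NULL, noise_floor_db = 10,
                              fs = 62500, duration = 0.6, seed = s)
    measure_dp(rec)$snr
  }, numeric(1))
  expect_lt(mean(snrs > 1), 0.9)
  expect_lt(abs(median(snrs) - 1), 0.5)
})

test_that("DP bin colliding with a primary is a configuration error", {
  rec <- simulate_ear_canal(12000, 60, seed = 1)
  rec$primaries$dp_frequency <- rec$primaries$f1
  expect_error(measure_dp(rec), "collides")
})

test_that("threshold calling: forced crossing, censoring, monotonicity", {
  mk <- function(snr, lvl, seg = snr) {
    structure(list(dp_level = 10, noise_floor = 0, snr = snr,
                   snr_segments = rep(seg, 3), f2_level = lvl,
                   dp_frequency = 8000), class = "dpoae_measurement")
  }
  ms <- lapply(seq(20, 80, 5), function(L) mk(if (L >= 50) 5 else 0.5, L))
  res <- dpoae_threshold(ms)
  expect_equal(res$threshold_db, 50)

  none <- lapply(seq(20, 80, 5), function(L) mk(0.4, L))
  expect_true(dpoae_threshold(none)$censored)

  # raising the emission at every level can only lower the threshold
  ms_hi <- lapply(seq(20, 80, 5), function(L) mk(if (L >= 40) 5 else 0.5, L))
  expect_lte(dpoae_threshold(ms_hi)$threshold_db,
             dpoae_threshold(ms)$threshold_db)
  expect_error(dpoae_threshold(list()), "non-empty")
})

test_that("planted ladder thresholds are recovered within one step", {
  ok <- 0
  for (s in 1:15) {
    lad <- simulate_dpoae_ladder(f2 = 12000, threshold_db = 50, fs = 62500,
                                 duration = 0.6, seed = 700 + s)
    th <- dpoae_threshold(lapply(lad$recordings, measure_dp))
    if (!th$censored && abs(th$threshold_db - 50) <= 5) ok <- ok + 1
  }
  expect_gte(ok, 13)
})

test_that("ear-canal synthesis is bit-identical under a fixed seed", {
  a <- simulate_ear_canal(12000, 60, dp_level = 20, noise_floor_db = 0,
                          fs = 62500, duration = 0.6, seed = 5)
  b <- simulate_ear_canal(12000, 60, dp_level = 20, noise_floor_db = 0,
                          fs = 62500, duration = 0.6, seed = 5)
  expect_identical(a$samples, b$samples)
})
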