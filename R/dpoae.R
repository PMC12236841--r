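# DPOAE primary-tone design, 2f1-f2 extraction and threshold calling.
#
# Calibration convention: a pure tone of amplitude a corresponds to
# 20*log10(a / p_ref) dB SPL with a single configurable reference constant
# p_ref (default 1). All level arithmetic is relative, so the absolute value
# of p_ref is immaterial.

#' Design a DPOAE primary-tone pair
#'
#' Standard primary geometry: `f1 = f2 / 1.2`, the f2 level 10 dB below the
#' f1 level, distortion product at `2*f1 - f2`.
#'
#' @param f2 f2 frequency in Hz.
#' @param L1 f1 level in dB SPL.
#' @param ratio f2/f1 ratio (default 1.2).
#' @return list of class `"primary_pair"`: `f1`, `f2`, `L1`, `L2`,
#'   `dp_frequency`.
#' @examples
#' design_primaries(16000, 70)  # f1 13333.33 Hz, L2 60 dB, dp 10666.67 Hz
#' @export
design_primaries <- function(f2, L1, ratio = 1.2) {
  check_scalar_pos(f2, "f2")
  abort_if(ratio <= 1, "`ratio` must exceed 1")
  f1 <- f2 / ratio
  dp <- 2 * f1 - f2
  abort_if(dp <= 0, "distortion-product frequency 2*f1 - f2 is not positive")
  structure(list(f1 = f1, f2 = f2, L1 = L1, L2 = L1 - 10,
                 dp_frequency = dp, ratio = ratio),
            class = "primary_pair")
}

#' Spectral-analysis configuration for DPOAE measurement
#'
#' Welch-style averaged amplitude spectrum: the recording is split into
#' `n_segments` non-overlapping segments, each windowed and Fourier
#' transformed; bin amplitudes are averaged across segments. The default
#' 3 x 0.5 s segments give 2 Hz bins at the 250 kHz (4 us) sampling of the
#' standard acquisition.
#'
#' @param n_segments number of Welch segments (default 3).
#' @param window `"hann"` (default) or `"rect"`.
#' @param n_side noise-floor bins per side of the DP bin (default 5).
#' @param guard guard bins excluded next to the DP and primary bins
#'   (default 1).
#' @param amp_eps numerical amplitude floor for silent recordings.
#' @return list of class `"dp_spec_cfg"`.
#' @export
dp_spec_cfg <- function(n_segments = 3, window = c("hann", "rect"),
                        n_side = 5, guard = 1, amp_eps = 1e-10) {
  structure(list(n_segments = as.integer(n_segments),
                 window = match.arg(window), n_side = as.integer(n_side),
                 guard = as.integer(guard), amp_eps = amp_eps),
            class = "dp_spec_cfg")
}

window_values <- function(window, n) {
  switch(window,
         hann = 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)),
         rect = rep(1, n))
}

#' Welch-averaged amplitude spectrum
#'
#' @param x numeric samples.
#' @param fs sampling rate in Hz.
#' @param cfg a [dp_spec_cfg()].
#' @return list: `freq` (Hz), `amp` (mean amplitude per bin across segments,
#'   calibrated so a full-scale pure tone at a bin centre reads its time
#'   -domain amplitude), `amp_segments` (bins x segments matrix),
#'   `seg_len`.
#' @export
welch_amplitude_spectrum <- function(x, fs, cfg = dp_spec_cfg()) {
  n <- length(x)
  seg_len <- n %/% cfg$n_segments
  abort_if(seg_len < 8, "recording too short for the configured segments")
  w <- window_values(cfg$window, seg_len)
  nbin <- seg_len %/% 2
  amps <- vapply(seq_len(cfg$n_segments), function(s) {
    seg <- x[((s - 1) * seg_len + 1):(s * seg_len)]
    X <- fft(seg * w)
    (2 * Mod(X[seq_len(nbin)]) / sum(w))
  }, numeric(nbin))
  list(freq = (seq_len(nbin) - 1) * fs / seg_len,
       amp = rowMeans(amps), amp_segments = amps, seg_len = seg_len)
}

# time-domain noise SD that produces an expected measured floor of
# `floor_db` under the given analysis configuration (Rayleigh-mean algebra
# for windowed white noise)
noise_sigma_for_floor <- function(floor_db, fs, duration, cfg, p_ref = 1) {
  seg_len <- floor(fs * duration) %/% cfg$n_segments
  w <- window_values(cfg$window, seg_len)
  db_to_amp(floor_db, p_ref) * sum(w) / sqrt(pi * sum(w^2))
}

#' Simulate an ear-canal recording with primaries and optional DP
#'
#' Signal model: `tone(f1, L1) + tone(f2, L1 - 10) + tone(2f1 - f2,
#' dp_level)` plus Gaussian noise whose expected measured floor under the
#' `cfg` analysis equals `noise_floor_db`.
#'
#' @param f2 f2 frequency in Hz.
#' @param L1 f1 level in dB SPL (f2 is played 10 dB lower).
#' @param dp_level planted DP level in dB SPL, or `NULL` for no emission.
#' @param noise_floor_db expected measured noise floor in dB SPL, or `NULL`
#'   to disable noise.
#' @param fs sampling rate in Hz (default 250000, i.e. 4 us sampling).
#' @param duration recording length in s (default 1.5 = 3 x 0.5 s segments).
#' @param ratio f2/f1 ratio.
#' @param p_ref amplitude reference for the dB SPL convention.
#' @param cfg analysis configuration the noise floor is calibrated against.
#' @param seed integer seed (noise only; tones are deterministic).
#' @return list of class `"pressure_recording"`: `samples`, `fs`,
#'   `primaries`, `p_ref`, `seed`.
#' @export
simulate_ear_canal <- function(f2, L1, dp_level = NULL, noise_floor_db = NULL,
                               fs = 250000, duration = 1.5, ratio = 1.2,
                               p_ref = 1, cfg = dp_spec_cfg(), seed = 1) {
  pp <- design_primaries(f2, L1, ratio = ratio)
  abort_if(fs <= 2 * max(pp$f1, pp$f2), "`fs` must exceed twice the primaries")
  abort_if(duration * pp$dp_frequency < 10,
           "duration must cover >= 10 periods of the DP component")
  n <- floor(fs * duration)
  t <- (seq_len(n) - 1) / fs
  x <- db_to_amp(pp$L1, p_ref) * sin(2 * pi * pp$f1 * t) +
    db_to_amp(pp$L2, p_ref) * sin(2 * pi * pp$f2 * t)
  if (!is.null(dp_level))
    x <- x + db_to_amp(dp_level, p_ref) * sin(2 * pi * pp$dp_frequency * t)
  if (!is.null(noise_floor_db)) {
    sigma <- noise_sigma_for_floor(noise_floor_db, fs, duration, cfg, p_ref)
    x <- x + withr::with_seed(seed, rnorm(n, 0, sigma))
  }
  structure(list(samples = x, fs = fs, primaries = pp, p_ref = p_ref,
                 seed = seed),
            class = "pressure_recording")
}

#' Measure the 2f1-f2 distortion product and noise floor
#'
#' The DP level is the calibrated amplitude at the spectral bin nearest
#' `2f1 - f2`; the noise floor is the mean amplitude of `n_side` bins on
#' each side of the DP bin, separated by a guard bin and excluding bins
#' within the guard of the primaries. SNR is the ratio of linear amplitudes;
#' per-segment SNRs are retained so threshold calling can demand a
#' repeatable emission.
#'
#' @param recording a `"pressure_recording"` (or list with `samples`, `fs`,
#'   `p_ref`).
#' @param primaries a [design_primaries()] pair; defaults to the recording's.
#' @param cfg a [dp_spec_cfg()].
#' @return list of class `"dpoae_measurement"`: `dp_level`, `noise_floor`
#'   (dB SPL), `snr` (linear), `snr_segments`, `f2_level`, `dp_frequency`.
#' @export
measure_dp <- function(recording, primaries = NULL, cfg = dp_spec_cfg()) {
  primaries <- primaries %||% recording$primaries
  abort_if(is.null(primaries), "no primary-pair metadata available")
  p_ref <- recording$p_ref %||% 1
  sp <- welch_amplitude_spectrum(recording$samples, recording$fs, cfg)
  df <- sp$freq[2] - sp$freq[1]

  bin_of <- function(f) which.min(abs(sp$freq - f))
  b_dp <- bin_of(primaries$dp_frequency)
  b_f1 <- bin_of(primaries$f1)
  b_f2 <- bin_of(primaries$f2)
  abort_if(b_dp == b_f1 || b_dp == b_f2,
           "DP bin collides with a primary bin; use a longer analysis window")

  cand <- c((b_dp - cfg$guard - cfg$n_side):(b_dp - cfg$guard - 1),
            (b_dp + cfg$guard + 1):(b_dp + cfg$guard + cfg$n_side))
  cand <- cand[cand >= 2 & cand <= length(sp$freq)]
  cand <- cand[abs(cand - b_f1) > cfg$guard & abs(cand - b_f2) > cfg$guard]
  abort_if(length(cand) == 0, "no usable noise-floor bins")

  dp_amp <- max(sp$amp[b_dp], cfg$amp_eps)
  floor_amp <- max(mean(sp$amp[cand]), cfg$amp_eps)
  snr_seg <- vapply(seq_len(ncol(sp$amp_segments)), function(s) {
    a <- sp$amp_segments[, s]
    max(a[b_dp], cfg$amp_eps) / max(mean(a[cand]), cfg$amp_eps)
  }, numeric(1))

  structure(list(dp_level = amp_to_db(dp_amp, p_ref),
                 noise_floor = amp_to_db(floor_amp, p_ref),
                 snr = dp_amp / floor_amp, snr_segments = snr_seg,
                 f2_level = primaries$L2, dp_frequency = primaries$dp_frequency,
                 bin_hz = df),
            class = "dpoae_measurement")
}

#' @export
print.dpoae_measurement <- function(x, ...) {
  cat(sprintf("DPOAE @ %g Hz: %.1f dB SPL (floor %.1f dB, SNR %.2f) at f2 level %g dB\n",
              x$dp_frequency, x$dp_level, x$noise_floor, x$snr, x$f2_level))
  invisible(x)
}

#' Call the DPOAE threshold from a level ladder
#'
#' The criterion "lowest f2 level at which the signal-to-noise-floor ratio
#' exceeds 1" is applied on linear amplitudes. Because a single noise bin
#' exceeds the mean of its neighbours about half the time, the default
#' `"sustained"` rule additionally requires the criterion to hold at every
#' higher tested level, and `require_segments = TRUE` demands SNR > 1 in
#' each Welch segment individually (the emission must be repeatable, as for
#' the ABR criterion). `rule = "first"` applies the literal first-crossing
#' reading.
#'
#' @param measurements list of `"dpoae_measurement"`s ordered by strictly
#'   ascending `f2_level`.
#' @param snr_min SNR criterion (default 1, linear).
#' @param rule `"sustained"` (default) or `"first"`.
#' @param require_segments demand the criterion in every Welch segment
#'   (default TRUE).
#' @return `"threshold_result"` on the f2-level grid (censored when no level
#'   qualifies).
#' @export
dpoae_threshold <- function(measurements, snr_min = 1,
                            rule = c("sustained", "first"),
                            require_segments = TRUE) {
  rule <- match.arg(rule)
  abort_if(length(measurements) == 0, "`measurements` must be non-empty")
  lv <- vapply(measurements, function(m) m$f2_level, numeric(1))
  abort_if(any(diff(lv) <= 0), "f2 levels must be strictly ascending")
  responding <- vapply(measurements, function(m) {
    ok <- m$snr > snr_min
    if (require_segments) ok <- ok && all(m$snr_segments > snr_min)
    ok
  }, logical(1))
  names(responding) <- lv
  idx <- if (rule == "sustained") {
    s <- rev(cumprod(rev(responding))) > 0
    if (any(s)) which(s)[1] else NA_integer_
  } else {
    if (any(responding)) which(responding)[1] else NA_integer_
  }
  if (is.na(idx)) {
    structure(list(threshold_db = NA_real_, censored = TRUE,
                   responding = responding,
                   criteria = list(snr_min = snr_min, rule = rule,
                                   require_segments = require_segments)),
              class = "threshold_result")
  } else {
    structure(list(threshold_db = lv[idx], censored = FALSE,
                   responding = responding,
                   criteria = list(snr_min = snr_min, rule = rule,
                                   require_segments = require_segments)),
              class = "threshold_result")
  }
}

#' Simulate a DPOAE growth ladder with a planted emission threshold
#'
#' One recording per f2 level: below the planted threshold no emission is
#' present; at and above it the DP level starts `margin_db` above the noise
#' floor and grows with the f2 level.
#'
#' @param f2 f2 frequency in Hz.
#' @param levels f2 levels (dB SPL), ascending 5-dB grid by default.
#' @param threshold_db planted emission threshold on the f2-level axis.
#' @param noise_floor_db noise floor (dB SPL, default 0).
#' @param margin_db DP level above the floor at threshold (default 6 dB).
#' @param growth_db_per_db DP growth slope above threshold (default 1.2).
#' @param fs,duration,cfg acquisition/analysis settings (see
#'   [simulate_ear_canal()]).
#' @param seed integer seed.
#' @return list of class `"dpoae_ladder"`: `recordings` (one per level),
#'   `levels`, `threshold_db`, `f2`.
#' @export
simulate_dpoae_ladder <- function(f2 = 12000, levels = seq(20, 80, by = 5),
                                  threshold_db = 50, noise_floor_db = 0,
                                  margin_db = 6, growth_db_per_db = 1.2,
                                  fs = 250000, duration = 1.5,
                                  cfg = dp_spec_cfg(), seed = 1) {
  abort_if(length(levels) == 0, "`levels` must be non-empty")
  levels <- sort(levels)
  recordings <- lapply(seq_along(levels), function(i) {
    L2 <- levels[i]
    dp <- if (L2 >= threshold_db)
      noise_floor_db + margin_db + growth_db_per_db * (L2 - threshold_db)
    else NULL
    simulate_ear_canal(f2 = f2, L1 = L2 + 10, dp_level = dp,
                       noise_floor_db = noise_floor_db, fs = fs,
                       duration = duration, cfg = cfg,
                       seed = derive_seed(seed, i))
  })
  structure(list(recordings = recordings, levels = levels,
                 threshold_db = threshold_db, f2 = f2),
            class = "dpoae_ladder")
}
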