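# ABR analysis: epoch averaging, wave-1 metrics, threshold detection.

#' Average ABR epochs into a waveform
#'
#' Arithmetic mean across epochs. Stimulus polarity alternation is an
#' acquisition device: the neural response is polarity-invariant while any
#' electrical stimulus artifact flips sign, so it cancels in the average.
#' Polarity labels are used only for bookkeeping (balanced split-half
#' sub-averages). A zero-phase 0.3-3 kHz bandpass mirroring the hardware
#' passband can be applied to raw epochs.
#'
#' @param epochs numeric matrix, one epoch per column.
#' @param fs sampling rate in Hz.
#' @param polarity optional vector of +1/-1 per epoch (default alternating).
#' @param level_db,frequency_khz stimulus metadata.
#' @param t_pre_ms pre-stimulus baseline duration contained in each epoch
#'   (default 0; the time axis starts at `-t_pre_ms`).
#' @param bandpass apply the 0.3-3 kHz zero-phase Butterworth bandpass to
#'   each epoch before averaging (default FALSE).
#' @return an `"abr_waveform"` with split-half sub-averages (`half_a`,
#'   `half_b`, polarity-balanced interleaved halves).
#' @export
average_epochs <- function(epochs, fs, polarity = NULL, level_db = NA,
                           frequency_khz = NA, t_pre_ms = 0,
                           bandpass = FALSE) {
  abort_if(!is.matrix(epochs) || ncol(epochs) < 2,
           "`epochs` must be a matrix with >= 2 columns of equal length")
  n_ep <- ncol(epochs)
  if (is.null(polarity)) polarity <- rep(c(1, -1), length.out = n_ep)
  abort_if(length(polarity) != n_ep,
           "`polarity` must have one entry per epoch")
  if (isTRUE(bandpass)) {
    bf <- signal::butter(2, c(300, 3000) / (fs / 2), type = "pass")
    epochs <- apply(epochs, 2, function(e) signal::filtfilt(bf, e))
  }
  half_id <- rep(rep(c(1L, 2L), each = 2L), length.out = n_ep)
  dt_ms <- 1000 / fs
  t_ms <- seq(-t_pre_ms, by = dt_ms, length.out = nrow(epochs))
  structure(list(samples = rowMeans(epochs), t_ms = t_ms, fs = fs,
                 level_db = level_db, frequency_khz = frequency_khz,
                 n_epochs_averaged = n_ep,
                 half_a = rowMeans(epochs[, half_id == 1L, drop = FALSE]),
                 half_b = rowMeans(epochs[, half_id == 2L, drop = FALSE])),
            class = "abr_waveform")
}

#' Wave-1 amplitude and latency of an averaged ABR waveform
#'
#' Amplitude is the peak-to-peak excursion in the wave-1 search window: the
#' default `"p1_trough"` convention takes the window maximum (P1) minus the
#' following minimum (N1), which matches the max-minus-min reading of
#' peak-to-peak while preventing wave-2 structure from supplying the peak;
#' `"global"` takes max minus min anywhere in the window. Latency is the time
#' of the P1 maximum.
#'
#' @param w an `"abr_waveform"`.
#' @param window_ms wave-1 search window in ms post-onset (default 1.0-2.5).
#' @param mode `"p1_trough"` (default) or `"global"`.
#' @return list of class `"wave1_metrics"`: `amplitude_uv` (>= 0),
#'   `latency_ms`.
#' @export
wave1_metrics <- function(w, window_ms = c(1.0, 2.5),
                          mode = c("p1_trough", "global")) {
  mode <- match.arg(mode)
  idx <- which(w$t_ms >= window_ms[1] & w$t_ms <= window_ms[2])
  abort_if(length(idx) == 0, "wave-1 window contains no samples")
  s <- w$samples[idx]
  imax <- which.max(s)
  amplitude <- if (mode == "p1_trough")
    s[imax] - min(s[imax:length(s)])
  else max(s) - min(s)
  structure(list(amplitude_uv = amplitude,
                 latency_ms = w$t_ms[idx][imax]),
            class = "wave1_metrics")
}

#' Detect the ABR threshold of a level series
#'
#' Formalizes "lowest level with a repeatable wave 1": a level responds when
#' (a) its wave-1 peak-to-peak amplitude exceeds `snr_k` times the RMS of the
#' pre-stimulus baseline of the averaged waveform and (b) its two
#' polarity-balanced split-half sub-averages correlate at least `r_min`
#' inside the wave window. The threshold is the lowest level such that it
#' and every higher tested level respond; if no level up to the maximum
#' tested (80 dB SPL in the standard protocol) responds, the result is
#' censored.
#'
#' @param series an `"abr_series"`.
#' @param snr_k amplitude criterion multiplier (default 3).
#' @param r_min split-half correlation criterion (default 0.5).
#' @param window_ms wave-1 window (default 1.0-2.5 ms).
#' @param mode peak convention passed to [wave1_metrics()].
#' @return list of class `"threshold_result"`: `threshold_db` (NA when
#'   censored), `censored`, `responding` (named logical per level),
#'   `criteria` (the settings used).
#' @export
detect_threshold <- function(series, snr_k = 3, r_min = 0.5,
                             window_ms = c(1.0, 2.5), mode = "p1_trough") {
  abort_if(!inherits(series, "abr_series"), "`series` must be an abr_series")
  abort_if(length(series$waveforms) < 2, "need >= 2 levels")

  responding <- vapply(series$waveforms, function(w) {
    m <- wave1_metrics(w, window_ms = window_ms, mode = mode)
    base <- w$samples[w$t_ms < 0]
    noise_rms <- if (length(base)) rms(base) else 0
    amp_ok <- m$amplitude_uv > snr_k * noise_rms && m$amplitude_uv > 0
    widx <- which(w$t_ms >= window_ms[1] & w$t_ms <= window_ms[2])
    a <- w$half_a[widx]; b <- w$half_b[widx]
    rep_ok <- if (sd(a) == 0 || sd(b) == 0) identical(a, b) && any(a != 0)
    else cor(a, b) >= r_min
    amp_ok && rep_ok
  }, logical(1))
  names(responding) <- series$levels

  sustained <- rev(cumprod(rev(responding))) > 0
  if (any(sustained)) {
    thr <- series$levels[which(sustained)[1]]
    censored <- FALSE
  } else {
    thr <- NA_real_
    censored <- TRUE
  }
  structure(list(threshold_db = thr, censored = censored,
                 responding = responding,
                 criteria = list(snr_k = snr_k, r_min = r_min,
                                 window_ms = window_ms, mode = mode)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$censored) cat("Threshold: censored (no repeatable response)\n")
  else cat(sprintf("Threshold: %g dB SPL\n", x$threshold_db))
  invisible(x)
}
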