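# Synthetic ABR epoch/waveform generation with a planted wave-1 threshold.

#' Default ABR wave template
#'
#' Sum-of-Gaussians template for the first milliseconds of a tone-evoked ABR:
#' wave-1 positive peak (P1) and trough (N1) followed by smaller wave-2/3
#' structure. Amplitudes are in uV at unit scale; the planted wave-1
#' peak-to-peak amplitude at scale 1 is `P1 + |N1|`.
#'
#' @param peaks data.frame with columns `t_ms`, `sigma_ms`, `amp_uv`.
#' @return object of class `"abr_template"`; callable via
#'   [abr_template_wave()].
#' @export
abr_template <- function(peaks = data.frame(
  t_ms = c(1.5, 2.1, 2.9, 3.4, 4.0),
  sigma_ms = c(0.16, 0.22, 0.20, 0.25, 0.25),
  amp_uv = c(1.0, -0.8, 0.6, -0.4, 0.45))) {
  structure(list(peaks = peaks), class = "abr_template")
}

#' Evaluate an ABR template on a time axis
#'
#' @param template an [abr_template()].
#' @param t_ms numeric vector of times (ms, relative to stimulus onset).
#' @return numeric vector of uV values at unit scale.
#' @export
abr_template_wave <- function(template, t_ms) {
  w <- numeric(length(t_ms))
  for (i in seq_len(nrow(template$peaks))) {
    p <- template$peaks[i, ]
    w <- w + p$amp_uv * exp(-0.5 * ((t_ms - p$t_ms) / p$sigma_ms)^2)
  }
  w
}

# planted wave-1 peak-to-peak amplitude of a template at unit scale, computed
# on a fine grid over the wave-1 window
template_p2p <- function(template, window_ms = c(1.0, 2.5)) {
  t <- seq(window_ms[1], window_ms[2], by = 0.001)
  w <- abr_template_wave(template, t)
  imax <- which.max(w)
  max(w) - min(w[imax:length(w)])
}

#' Simulate a level series of averaged ABR waveforms
#'
#' Generates per-level epoch sets (alternating stimulus polarity), averages
#' them, and returns the level-graded series. Below the planted threshold the
#' epochs contain noise only; at and above it the template grows linearly
#' with dB above threshold. Split-half sub-averages (balanced in polarity)
#' are stored with each waveform for repeatability testing. An optional
#' stimulus artifact flips with polarity and therefore cancels in the
#' full average.
#'
#' @param threshold_db planted wave-1 threshold in dB SPL; values above
#'   `max(levels)` yield a pure-noise series.
#' @param levels stimulus levels in dB SPL (default 20-80 in 5 dB steps).
#' @param noise_sigma_uv per-epoch noise SD in uV (default 0.5).
#' @param n_epochs epochs averaged per level (default 1024).
#' @param fs sampling rate in Hz (default 25000).
#' @param frequency_khz stimulus frequency metadata.
#' @param template an [abr_template()].
#' @param base_uv wave-1 template scale at threshold (default 0.5).
#' @param growth_uv_per_db template scale growth per dB above threshold
#'   (default 0.15).
#' @param t_pre_ms,t_post_ms pre-stimulus baseline and post-onset record
#'   lengths (defaults 1 and 9 ms; the response window of interest is the
#'   first ~7 ms).
#' @param artifact_uv amplitude of a polarity-following stimulus artifact at
#'   t = 0 (default 0 = disabled).
#' @param seed integer seed.
#' @return object of class `"abr_series"`: list of `"abr_waveform"`s (fields
#'   `samples`, `t_ms`, `fs`, `level_db`, `frequency_khz`,
#'   `n_epochs_averaged`, `half_a`, `half_b`), plus `levels`, `threshold_db`
#'   (the planted truth), `seed`.
#' @export
simulate_abr_series <- function(threshold_db = 45,
                                levels = seq(20, 80, by = 5),
                                noise_sigma_uv = 0.5, n_epochs = 1024,
                                fs = 25000, frequency_khz = 16,
                                template = abr_template(), base_uv = 0.5,
                                growth_uv_per_db = 0.15,
                                t_pre_ms = 1, t_post_ms = 9,
                                artifact_uv = 0, seed = 1) {
  abort_if(length(levels) == 0, "`levels` must be non-empty")
  abort_if(noise_sigma_uv < 0, "`noise_sigma_uv` must be >= 0")
  abort_if(n_epochs < 2, "`n_epochs` must be >= 2")
  levels <- sort(unique(levels))

  dt_ms <- 1000 / fs
  t_ms <- seq(-t_pre_ms, t_post_ms - dt_ms, by = dt_ms)
  ns <- length(t_ms)
  artifact <- if (artifact_uv != 0)
    artifact_uv * exp(-0.5 * ((t_ms - 0) / 0.1)^2) else numeric(ns)

  withr::with_seed(seed, {
    waveforms <- lapply(levels, function(L) {
      scale <- if (L >= threshold_db)
        base_uv + growth_uv_per_db * (L - threshold_db) else 0
      signal <- if (scale > 0) {
        w <- numeric(ns)
        post <- t_ms >= 0
        w[post] <- scale * abr_template_wave(template, t_ms[post])
        w
      } else numeric(ns)

      polarity <- rep(c(1, -1), length.out = n_epochs)
      # epochs in columns; accumulate sums rather than storing all epochs
      half_id <- rep(rep(c(1L, 2L), each = 2L), length.out = n_epochs)
      sum_a <- numeric(ns); sum_b <- numeric(ns)
      n_a <- sum(half_id == 1L); n_b <- n_epochs - n_a
      if (noise_sigma_uv > 0) {
        noise <- matrix(rnorm(ns * n_epochs, 0, noise_sigma_uv), ns, n_epochs)
      } else {
        noise <- matrix(0, ns, n_epochs)
      }
      epochs <- noise + signal + outer(artifact, polarity)
      sum_a <- rowSums(epochs[, half_id == 1L, drop = FALSE])
      sum_b <- rowSums(epochs[, half_id == 2L, drop = FALSE])
      structure(list(samples = (sum_a + sum_b) / n_epochs, t_ms = t_ms,
                     fs = fs, level_db = L, frequency_khz = frequency_khz,
                     n_epochs_averaged = n_epochs,
                     half_a = sum_a / n_a, half_b = sum_b / n_b),
                class = "abr_waveform")
    })
    structure(list(waveforms = waveforms, levels = levels,
                   threshold_db = threshold_db, frequency_khz = frequency_khz,
                   seed = seed),
              class = "abr_series")
  })
}

#' @export
print.abr_series <- function(x, ...) {
  cat(sprintf("ABR series at %g kHz: %d levels (%g-%g dB SPL), planted threshold %g dB\n",
              x$frequency_khz, length(x$levels), min(x$levels), max(x$levels),
              x$threshold_db))
  invisible(x)
}
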