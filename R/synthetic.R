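#' Specification of a synthetic ICG record
#'
#' Describes a quasi-periodic train of dZ/dt-like beats with known
#' ground truth. Each beat is a sum of four Gaussian lobes: a small
#' negative atrial (A) wave just before the systolic upstroke, the
#' dominant positive C wave, the negative X trough of aortic valve
#' closing, and a small positive diastolic O wave. Ground-truth B, C
#' and X positions are read off the noiseless template, so additive
#' noise and baseline wander never move the truth.
#'
#' Timing defaults place the A wave 70 ms before C (giving a B-to-C
#' interval of about 70 ms, within the resting physiological range),
#' the X trough 110 ms after C and the O wave at 220 ms. Lobe widths
#' are full widths at half maximum in ms.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Record duration in seconds.
#' @param hr_mean_bpm,hr_sd_bpm Mean and beat-to-beat standard
#'   deviation of the heart rate; each inter-beat interval is drawn as
#'   `60 / N(hr_mean, hr_sd)` seconds, truncated below at 0.3 s.
#' @param c_amplitude Amplitude of the C lobe (Ohm/s scale; 1.5 is a
#'   typical adult dZ/dt_max).
#' @param amplitude_jitter Fractional per-beat amplitude standard
#'   deviation applied to the whole template.
#' @param a_wave_amplitude,x_trough_depth,o_wave_amplitude Magnitudes
#'   of the A, X and O lobes (A and X enter negatively).
#' @param component_centers_ms Named vector of lobe centres relative to
#'   C, ms (`a`, `x`, `o`).
#' @param component_widths_ms Named vector of lobe full widths at half
#'   maximum, ms (`a`, `c`, `x`, `o`).
#' @param noise_sd Standard deviation of additive white Gaussian noise,
#'   in signal units. Ignored when `snr_db` is given.
#' @param snr_db When non-`NULL`, the noise level is set so that the
#'   clean beat train has this signal-to-noise ratio in dB.
#' @param wander_amplitude,wander_freq_hz Amplitude and frequency of a
#'   sinusoidal baseline wander (respiratory-band drift).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 250, duration_s = 60, hr_mean_bpm = 75,
                       hr_sd_bpm = 3, c_amplitude = 1.5,
                       amplitude_jitter = 0.07,
                       a_wave_amplitude = 0.25, x_trough_depth = 0.5,
                       o_wave_amplitude = 0.25,
                       component_centers_ms = c(a = -70, x = 110, o = 220),
                       component_widths_ms = c(a = 30, c = 50, x = 45,
                                               o = 60),
                       noise_sd = 0, snr_db = NULL,
                       wander_amplitude = 0.1, wander_freq_hz = 0.3,
                       seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, hr_mean_bpm > 20, hr_mean_bpm < 250,
            hr_sd_bpm >= 0, noise_sd >= 0, amplitude_jitter >= 0,
            wander_amplitude >= 0,
            all(c("a", "x", "o") %in% names(component_centers_ms)),
            all(c("a", "c", "x", "o") %in% names(component_widths_ms)))
  structure(list(fs = fs, duration_s = duration_s,
                 hr_mean_bpm = hr_mean_bpm, hr_sd_bpm = hr_sd_bpm,
                 c_amplitude = c_amplitude,
                 amplitude_jitter = amplitude_jitter,
                 a_wave_amplitude = a_wave_amplitude,
                 x_trough_depth = x_trough_depth,
                 o_wave_amplitude = o_wave_amplitude,
                 component_centers_ms = component_centers_ms,
                 component_widths_ms = component_widths_ms,
                 noise_sd = noise_sd, snr_db = snr_db,
                 wander_amplitude = wander_amplitude,
                 wander_freq_hz = wander_freq_hz,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' One-beat template with ground-truth offsets
#'
#' Builds the noiseless beat waveform and locates its fiducial points:
#' C at the global maximum, B at the local minimum nearest before C
#' (the notch between the A wave and the systolic upstroke), X at the
#' first local minimum after C.
#'
#' @param spec A [synth_spec()].
#' @return A list with `waveform` (numeric vector spanning -0.3 s to
#'   +0.3 s around C), and 1-based offsets `b_offset`, `c_offset`,
#'   `x_offset` into that vector, strictly ordered `b < c < x`.
#' @export
synth_beat_template <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- spec$fs
  tt <- seq(-0.30, 0.30, by = 1 / fs)
  sig <- spec$component_widths_ms / 1000 / (2 * sqrt(2 * log(2)))
  mu <- spec$component_centers_ms / 1000
  g <- function(m, s) exp(-0.5 * ((tt - m) / s)^2)
  w <- -spec$a_wave_amplitude * g(mu[["a"]], sig[["a"]]) +
        spec$c_amplitude * g(0, sig[["c"]]) -
        spec$x_trough_depth * g(mu[["x"]], sig[["x"]]) +
        spec$o_wave_amplitude * g(mu[["o"]], sig[["o"]])
  if (spec$c_amplitude <= 0 || max(w) <= 0)
    stop("template has no identifiable C lobe (c_amplitude must dominate)")
  c_off <- which.max(w)
  e <- find_extrema(w)
  b_cand <- e$minima[e$minima < c_off]
  x_cand <- e$minima[e$minima > c_off]
  if (!length(b_cand))
    stop("template has no local minimum before C; increase a_wave_amplitude")
  if (!length(x_cand))
    stop("template has no local minimum after C; increase x_trough_depth ",
         "or o_wave_amplitude")
  list(waveform = w, b_offset = max(b_cand), c_offset = c_off,
       x_offset = min(x_cand))
}

#' Generate a synthetic ICG record with ground-truth annotations
#'
#' Places amplitude-jittered copies of the beat template at intervals
#' drawn from the heart-rate law, fixes the ground-truth annotations
#' from the noiseless placement, then adds baseline wander and white
#' noise. Beats are placed only where the whole template fits, so the
#' record begins and ends without partial beats.
#'
#' @param spec A [synth_spec()].
#' @return A list with `signal` (an [icg_signal()]), `annotations` (an
#'   [icg_fiducials()] ground truth) and `noise_sd` (the noise level
#'   actually used, after any `snr_db` conversion).
#' @examples
#' gen <- synth_signal(synth_spec(duration_s = 20, seed = 3))
#' gen$annotations
#' @export
synth_signal <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  tm <- synth_beat_template(spec)
  fs <- spec$fs
  n <- as.integer(round(spec$duration_s * fs))
  L <- length(tm$waveform)
  if (n < L + as.integer(0.4 * fs))
    stop("duration_s too short to place a single beat (need at least ",
         round((L / fs + 0.4), 2), " s)")
  with_local_seed(spec$seed, {
    clean <- numeric(n)
    b <- c_ <- x <- integer(0)
    t_c <- 0.4
    repeat {
      start <- as.integer(round(t_c * fs)) - (tm$c_offset - 1L)
      if (start < 1L || start + L - 1L > n) break
      amp <- stats::rnorm(1, 1, spec$amplitude_jitter)
      ix <- start:(start + L - 1L)
      clean[ix] <- clean[ix] + amp * tm$waveform
      b <- c(b, start + tm$b_offset - 1L)
      c_ <- c(c_, start + tm$c_offset - 1L)
      x <- c(x, start + tm$x_offset - 1L)
      ibi <- 60 / stats::rnorm(1, spec$hr_mean_bpm, spec$hr_sd_bpm)
      t_c <- t_c + max(0.3, ibi)
    }
    if (!length(c_)) stop("no beats placed; increase duration_s")
    noise_sd <- if (!is.null(spec$snr_db))
      sqrt(mean(clean^2)) / 10^(spec$snr_db / 20) else spec$noise_sd
    wander <- spec$wander_amplitude *
      sin(2 * pi * spec$wander_freq_hz * seq_len(n) / fs)
    noisy <- clean + wander +
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    list(signal = icg_signal(noisy, fs, "synthetic dZ/dt"),
         annotations = icg_fiducials(b, c_, x, fs),
         noise_sd = noise_sd)
  })
}
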