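#' Subject constants for the Kubicek stroke-volume formula
#'
#' @param rho Specific resistance of blood in Ohm cm (typical range
#'   135-150).
#' @param length_cm Thoracic length between the voltage electrodes, cm.
#' @param z0 Base thoracic impedance in Ohm.
#' @return A list of class `subject_constants`.
#' @export
subject_constants <- function(rho = 150, length_cm = 30, z0 = 25) {
  stopifnot(rho > 0, length_cm > 0, z0 > 0)
  structure(list(rho = rho, length_cm = length_cm, z0 = z0),
            class = "subject_constants")
}

#' Left-ventricular ejection time of one beat
#'
#' The interval between the aortic valve opening (B) and closing (X).
#'
#' @param b_idx,x_idx Sample indices of the B and X points, `b_idx <
#'   x_idx`.
#' @param fs Sampling rate in Hz.
#' @return Time in seconds.
#' @export
lvet <- function(b_idx, x_idx, fs) {
  stopifnot(fs > 0)
  if (any(b_idx >= x_idx))
    stop("B must precede X (got b = ", b_idx[which(b_idx >= x_idx)[1L]],
         ", x = ", x_idx[which(b_idx >= x_idx)[1L]], ")")
  (x_idx - b_idx) / fs
}

#' Signal amplitude at the C point
#'
#' The C point marks the maximum rate of impedance change, so the dZ/dt
#' value there is the dZ/dt_max of the beat.
#'
#' @param signal An [icg_signal()].
#' @param c_idx Sample index of the C point.
#' @return The sample value (Ohm/s for a calibrated record).
#' @export
dzdt_max_at_c <- function(signal, c_idx) {
  stopifnot(inherits(signal, "icg_signal"))
  if (any(c_idx < 1L) || any(c_idx > length(signal$samples)))
    stop("c_idx outside the signal (length ", length(signal$samples), ")")
  signal$samples[c_idx]
}

#' Kubicek stroke volume
#'
#' `SV = rho * L^2 / Z0^2 * dZ/dt_max * LVET`, in millilitres
#' (Ohm cm * cm^2 / Ohm^2 * Ohm/s * s = cm^3).
#'
#' @param consts A [subject_constants()].
#' @param dzdt_max Maximum rate of impedance change, Ohm/s.
#' @param lvet_s Left-ventricular ejection time, s.
#' @return Stroke volume in mL.
#' @examples
#' stroke_volume(subject_constants(150, 30, 25), 1.5, 0.3)  # 97.2 mL
#' @export
stroke_volume <- function(consts, dzdt_max, lvet_s) {
  stopifnot(inherits(consts, "subject_constants"))
  if (any(dzdt_max < 0)) stop("dzdt_max must be nonnegative")
  if (any(lvet_s <= 0)) stop("lvet_s must be positive")
  consts$rho * consts$length_cm^2 / consts$z0^2 * dzdt_max * lvet_s
}

#' Heart rate from the C-point train
#'
#' @param c_indices Ascending sample indices of at least 2 C points.
#' @param fs Sampling rate in Hz.
#' @return Beats per minute, `60 * fs / mean(diff(c_indices))`.
#' @export
heart_rate <- function(c_indices, fs) {
  stopifnot(fs > 0)
  60 * fs / compute_cc_mean(c_indices)
}

#' Cardiac output
#'
#' @param mean_sv_ml Mean stroke volume in mL.
#' @param hr_bpm Heart rate in beats per minute.
#' @return Cardiac output in L/min.
#' @export
cardiac_output <- function(mean_sv_ml, hr_bpm) {
  if (any(mean_sv_ml <= 0) || any(hr_bpm <= 0))
    stop("stroke volume and heart rate must be positive")
  mean_sv_ml * hr_bpm / 1000
}

#' Pre-ejection period
#'
#' Time from electrical systole (ECG Q point, supplied externally) to
#' the aortic valve opening (ICG B point).
#'
#' @param q_idx,b_idx Sample indices with `q_idx < b_idx`.
#' @param fs Sampling rate in Hz.
#' @return Time in seconds.
#' @export
pep <- function(q_idx, b_idx, fs) {
  stopifnot(fs > 0)
  if (any(q_idx >= b_idx)) stop("Q must precede B")
  (b_idx - q_idx) / fs
}

#' Heather contractility index
#'
#' Interpreted as the dZ/dt amplitude at C divided by the Q-to-C time
#' (units Ohm/s^2); the classical definition of this index is
#' ambiguous, so the interpretation is explicit here.
#'
#' @param dzdt_max Amplitude at the C point, Ohm/s.
#' @param q_idx,c_idx Sample indices with `q_idx < c_idx`.
#' @param fs Sampling rate in Hz.
#' @return Index value in Ohm/s^2.
#' @export
heather_index <- function(dzdt_max, q_idx, c_idx, fs) {
  stopifnot(fs > 0)
  if (any(q_idx >= c_idx)) stop("Q must precede C")
  dzdt_max / ((c_idx - q_idx) / fs)
}

#' Per-beat hemodynamic metrics
#'
#' Computes LVET, dZ/dt_max and stroke volume for every beat of an
#' annotation set, plus the record-level heart rate and cardiac output.
#' Beats missing B or X yield `NA` for LVET and SV and are excluded
#' from the aggregates; clinical values are never interpolated.
#'
#' @param fiducials An [icg_fiducials()] annotation set.
#' @param signal The [icg_signal()] the annotations refer to.
#' @param consts A [subject_constants()].
#' @param q_indices Optional vector of externally supplied ECG Q indices
#'   (one per beat, `NA` allowed) enabling PEP and the Heather index.
#' @return A list of class `beat_metrics`: `beats` (data frame with one
#'   row per beat) and `summary` (list with `hr_bpm`, `mean_sv_ml`,
#'   `co_l_min`, `n_beats`, `n_complete`).
#' @export
beat_metrics <- function(fiducials, signal, consts = subject_constants(),
                         q_indices = NULL) {
  stopifnot(inherits(fiducials, "icg_fiducials"),
            inherits(signal, "icg_signal"))
  fs <- attr(fiducials, "fs")
  nb <- nrow(fiducials)
  df <- data.frame(beat = fiducials$beat, b = fiducials$b,
                   c = fiducials$c, x = fiducials$x,
                   lvet_s = NA_real_, dzdt_max = NA_real_, sv_ml = NA_real_)
  df$dzdt_max <- dzdt_max_at_c(signal, fiducials$c)
  ok <- !is.na(df$b) & !is.na(df$x)
  if (any(ok)) {
    df$lvet_s[ok] <- lvet(df$b[ok], df$x[ok], fs)
    pos <- ok & df$dzdt_max > 0
    df$sv_ml[pos] <- stroke_volume(consts, df$dzdt_max[pos], df$lvet_s[pos])
  }
  if (!is.null(q_indices)) {
    stopifnot(length(q_indices) == nb)
    qok <- !is.na(q_indices)
    df$pep_s <- NA_real_
    df$heather <- NA_real_
    bq <- qok & !is.na(df$b) & q_indices < df$b
    df$pep_s[bq] <- pep(q_indices[bq], df$b[bq], fs)
    cq <- qok & q_indices < df$c
    df$heather[cq] <- heather_index(df$dzdt_max[cq], q_indices[cq],
                                    df$c[cq], fs)
  }
  hr <- if (nb >= 2L) heart_rate(df$c, fs) else NA_real_
  mean_sv <- if (any(!is.na(df$sv_ml))) mean(df$sv_ml, na.rm = TRUE)
             else NA_real_
  co <- if (is.finite(hr) && is.finite(mean_sv) && mean_sv > 0)
          cardiac_output(mean_sv, hr) else NA_real_
  structure(list(beats = df,
                 summary = list(hr_bpm = hr, mean_sv_ml = mean_sv,
                                co_l_min = co, n_beats = nb,
                                n_complete = sum(ok))),
            class = "beat_metrics")
}

#' @export
print.beat_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<beat_metrics> %d beats (%d with full B/C/X)\n",
              s$n_beats, s$n_complete))
  cat(sprintf("  HR %.1f bpm | mean SV %.1f mL | CO %.2f L/min\n",
              s$hr_bpm, s$mean_sv_ml, s$co_l_min))
  invisible(x)
}
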