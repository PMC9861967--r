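#' Detection configuration for the fiducial-point pipeline
#'
#' @param refractory_ms Minimum separation between two accepted C
#'   detections, in milliseconds (default 200).
#' @param x_window_fraction Fraction of the mean C-to-C interval that
#'   bounds the X search window after each C point (default 0.15).
#' @param b_search_window_ms How far before C the B point is searched
#'   for (default 300 ms, a generous bound on pre-ejection timing).
#' @param c_snap_window_ms Half-width in ms of the window in which a
#'   detected C is snapped onto the maximum of the dZ/dt signal itself
#'   (default 40 ms = 10 samples at 250 Hz). Set `snap = FALSE` to
#'   report the raw detector-function peak instead.
#' @param threshold_init_fraction Fraction of the initial peak estimate
#'   used for the starting threshold (default 0.5).
#' @param threshold_fraction Fraction of the running peak-to-noise span
#'   added to the noise level to form the adaptive threshold
#'   (default 0.25, the classic two-level peak-detector constant).
#' @param threshold_update_weight Exponential-moving-average weight for
#'   the running peak and noise levels (default 0.125).
#' @param late_lobe_window_ms Discrimination window after each
#'   acceptance (default 360 ms): a candidate inside it is accepted
#'   only if it exceeds half the previous accepted peak, which rejects
#'   the diastolic (O-wave) lobes of the detection function without
#'   penalising genuine fast beats.
#' @param searchback Recover missed beats: when no detection has
#'   occurred for 1.66 times the running mean inter-detection interval,
#'   accept the best candidate above half the threshold in the gap.
#' @param snap Whether to snap C onto the dZ/dt maximum (default TRUE).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(refractory_ms = 200, x_window_fraction = 0.15,
                             b_search_window_ms = 300,
                             c_snap_window_ms = 40,
                             threshold_init_fraction = 0.5,
                             threshold_fraction = 0.25,
                             threshold_update_weight = 0.125,
                             late_lobe_window_ms = 360,
                             searchback = TRUE, snap = TRUE) {
  stopifnot(refractory_ms > 0, x_window_fraction > 0, x_window_fraction < 1,
            b_search_window_ms > 0, c_snap_window_ms >= 0,
            threshold_init_fraction > 0, threshold_fraction > 0,
            threshold_update_weight > 0, threshold_update_weight <= 1,
            late_lobe_window_ms >= 0)
  structure(list(refractory_ms = refractory_ms,
                 x_window_fraction = x_window_fraction,
                 b_search_window_ms = b_search_window_ms,
                 c_snap_window_ms = c_snap_window_ms,
                 threshold_init_fraction = threshold_init_fraction,
                 threshold_fraction = threshold_fraction,
                 threshold_update_weight = threshold_update_weight,
                 late_lobe_window_ms = late_lobe_window_ms,
                 searchback = isTRUE(searchback), snap = isTRUE(snap)),
            class = "detection_config")
}

check_imf_count <- function(imfset, need, what) {
  k <- n_imfs(imfset)
  if (k < need)
    stop(what, " needs at least ", need, " IMFs; the decomposition has ",
         k, " (longer or richer input required)")
  invisible(k)
}

#' C-point carrier: sum of EMD modes 1-4
#'
#' The C wave is the most prominent event of the cardiac cycle, and the
#' first four EMD modes carry essentially all of it; their sum is the
#' first stage of the C detector.
#'
#' @param imfset An `imf_set` from [emd()] with at least 4 modes.
#' @return Numeric vector `IMF1 + IMF2 + IMF3 + IMF4`.
#' @export
compute_cf11 <- function(imfset) {
  check_imf_count(imfset, 4L, "compute_cf11")
  rowSums(imfset$imfs[, 1:4, drop = FALSE])
}

#' Fast-oscillation mask: product of EMD modes 1-3
#'
#' Multiplying the three fastest modes suppresses the slow content of
#' the summed carrier and concentrates amplitude where all fast modes
#' are simultaneously large, i.e. at the C wave.
#'
#' @param imfset An `imf_set` from [emd()] with at least 3 modes.
#' @return Numeric vector `IMF1 * IMF2 * IMF3`.
#' @export
compute_cf12 <- function(imfset) {
  check_imf_count(imfset, 3L, "compute_cf12")
  imfset$imfs[, 1L] * imfset$imfs[, 2L] * imfset$imfs[, 3L]
}

#' C-detection function
#'
#' @param cf11 Output of [compute_cf11()].
#' @param cf12 Output of [compute_cf12()].
#' @return Nonnegative numeric vector `|cf11 * cf12|` whose peaks mark
#'   the C points.
#' @export
compute_cf1 <- function(cf11, cf12) {
  if (length(cf11) != length(cf12))
    stop("length mismatch: cf11 has ", length(cf11), ", cf12 has ",
         length(cf12))
  abs(cf11 * cf12)
}

#' X-detection function: weighted EEMD modes 3-5
#'
#' The aortic-valve-closing trough lives in the mid-order ensemble
#' modes; the weighting emphasises the slower ones. A decomposition with
#' fewer than five modes is padded with zero modes (with a warning)
#' rather than rejected.
#'
#' @param imfset An `imf_set` from [eemd()].
#' @return Numeric vector `IMF3 + 2 IMF4 + 4 IMF5`.
#' @export
compute_cf2 <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  k <- n_imfs(imfset)
  if (k < 3L)
    stop("compute_cf2 needs at least 3 IMFs; the decomposition has ", k)
  if (k < 5L)
    warning("compute_cf2: only ", k,
            " IMFs available; missing modes treated as zero")
  m <- function(j) if (k >= j) imfset$imfs[, j] else 0
  m(3L) + 2 * m(4L) + 4 * m(5L)
}

#' Adaptive-threshold C-point detection with refractory period
#'
#' Scans the local maxima of the (nonnegative) detection function `cf1`
#' with a two-level adaptive threshold: running peak and noise levels
#' are exponential moving averages of accepted peaks and rejected
#' candidates, and the threshold sits `threshold_fraction` of the way
#' from the noise level to the peak level. After an acceptance, further
#' candidates within the refractory period are ignored (they belong to
#' the same beat complex), so the first supra-threshold lobe of each
#' beat wins; the C point proper is then recovered by
#' [snap_c_to_signal()]. An optional search-back stage rescues beats
#' missed after a threshold excursion.
#'
#' @param cf1 Nonnegative detection function (see [compute_cf1()]).
#' @param fs Sampling rate in Hz.
#' @param config A [detection_config()].
#' @return A list of class `c_point_train` with `c_indices` (ascending,
#'   respecting the refractory separation), `cc_mean` (mean C-to-C gap
#'   in samples, `NA` with fewer than 2 points) and `threshold_state`
#'   (final `th`, `peak_level`, `noise_level`).
#' @export
detect_c_points <- function(cf1, fs, config = detection_config()) {
  stopifnot(fs > 0)
  if (any(cf1 < 0)) stop("cf1 must be nonnegative")
  n <- length(cf1)
  refr <- max(1L, as.integer(round(config$refractory_ms * fs / 1000)))
  empty <- structure(list(c_indices = integer(0), cc_mean = NA_real_,
                          threshold_state = NULL), class = "c_point_train")
  if (n < 3L || max(cf1) == 0) return(empty)
  cand <- find_extrema(cf1)$maxima
  if (!length(cand)) return(empty)

  init <- cf1[seq_len(min(as.integer(3 * fs), n))]
  peak_l <- max(init)
  noise_l <- mean(init)
  w <- config$threshold_update_weight
  frac <- config$threshold_fraction
  th <- noise_l + config$threshold_init_fraction * (peak_l - noise_l)
  det <- integer(0)
  rr <- numeric(0)

  lobe_win <- as.integer(round(config$late_lobe_window_ms * fs / 1000))
  last_peak <- NA_real_
  for (i in cand) {
    v <- cf1[i]
    late_lobe <- length(det) && i - det[length(det)] < lobe_win &&
      v < 0.5 * last_peak
    if (v >= th && !late_lobe) {
      # candidates inside the refractory window of the last acceptance are
      # lobes of the same beat complex: skip them without touching the
      # noise level
      if (!(length(det) && i - det[length(det)] < refr)) {
        det <- c(det, i)
        last_peak <- v
        peak_l <- (1 - w) * peak_l + w * v
        if (length(det) >= 2L)
          rr <- c(rr, det[length(det)] - det[length(det) - 1L])
      }
    } else {
      noise_l <- (1 - w) * noise_l + w * v
      if (config$searchback && length(rr) >= 2L && length(det)) {
        rr_mean <- mean(utils::tail(rr, 8L))
        if (i - det[length(det)] > 1.66 * rr_mean) {
          gap <- cand[cand > det[length(det)] + refr & cand < i]
          gap <- gap[cf1[gap] >= 0.5 * th]
          if (length(gap)) {
            gi <- gap[which.max(cf1[gap])]
            det <- sort(c(det, gi))
            last_peak <- cf1[gi]
            peak_l <- (1 - w) * peak_l + w * last_peak
          }
        }
      }
    }
    th <- noise_l + frac * (peak_l - noise_l)
  }
  structure(list(c_indices = det,
                 cc_mean = if (length(det) >= 2L) mean(diff(det))
                           else NA_real_,
                 threshold_state = list(th = th, peak_level = peak_l,
                                        noise_level = noise_l)),
            class = "c_point_train")
}

#' @export
print.c_point_train <- function(x, ...) {
  cat(sprintf("<c_point_train> %d C points, mean interval %s samples\n",
              length(x$c_indices),
              if (is.na(x$cc_mean)) "NA" else format(round(x$cc_mean, 1))))
  invisible(x)
}

#' Snap C detections onto the dZ/dt maximum
#'
#' The C point is defined on the ICG waveform itself (the greatest
#' amplitude of the cardiac cycle), while the detector works on a
#' derived function whose peak can sit a few samples off. This moves
#' each index to the signal maximum within a window around it.
#'
#' @param c_idx Integer vector of detected indices.
#' @param signal An [icg_signal()] (the preprocessed dZ/dt).
#' @param window_ms Half-width of the search window in ms; 0 disables
#'   the move.
#' @return Integer vector of snapped indices.
#' @export
snap_c_to_signal <- function(c_idx, signal, window_ms = 40) {
  stopifnot(inherits(signal, "icg_signal"))
  if (!length(c_idx)) return(integer(0))
  x <- signal$samples
  n <- length(x)
  if (any(c_idx < 1L | c_idx > n)) stop("c_idx outside the signal")
  hw <- as.integer(round(window_ms * signal$fs / 1000))
  if (hw == 0L) return(as.integer(c_idx))
  vapply(as.integer(c_idx), function(i) {
    lo <- max(1L, i - hw)
    hi <- min(n, i + hw)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
}

#' Mean interval between consecutive C points
#'
#' @param c_indices Ascending integer indices with at least 2 entries.
#' @return Mean of the consecutive differences, in samples.
#' @export
compute_cc_mean <- function(c_indices) {
  if (length(c_indices) < 2L)
    stop("compute_cc_mean needs at least 2 C points")
  if (is.unsorted(c_indices, strictly = TRUE))
    stop("c_indices must be strictly increasing")
  mean(diff(c_indices))
}

#' First derivative of a sampled series
#'
#' Central differences scaled to physical units (per second); one-sided
#' differences at the endpoints. Output length equals input length.
#'
#' @param x Numeric vector, length at least 3.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of the derivative.
#' @export
derivative <- function(x, fs) {
  n <- length(x)
  if (n < 3L) stop("derivative needs at least 3 samples")
  stopifnot(fs > 0)
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d
}

#' B point for one beat
#'
#' The aortic-valve opening is identified as the local maximum of the
#' first derivative of the fourth ensemble mode nearest before the C
#' point, within a bounded search window.
#'
#' @param imf4 The fourth EEMD mode (numeric vector), or its
#'   precomputed derivative if `is_derivative = TRUE`.
#' @param c_idx C index of the beat.
#' @param fs Sampling rate in Hz.
#' @param config A [detection_config()] (uses `b_search_window_ms`).
#' @param is_derivative Set to TRUE when `imf4` is already the
#'   derivative series.
#' @return Integer index, or `NA_integer_` when no local maximum of the
#'   derivative exists in the window.
#' @export
detect_b_point <- function(imf4, c_idx, fs, config = detection_config(),
                           is_derivative = FALSE) {
  d4 <- if (is_derivative) imf4 else derivative(imf4, fs)
  if (c_idx < 1L || c_idx > length(d4)) stop("c_idx outside the series")
  win <- as.integer(round(config$b_search_window_ms * fs / 1000))
  mx <- find_extrema(d4)$maxima
  mx <- mx[mx < c_idx & mx >= c_idx - win]
  if (!length(mx)) return(NA_integer_)
  max(mx)
}

#' X search interval after a C point
#'
#' @param c_idx C index of the beat.
#' @param cc_mean Mean C-to-C interval in samples (positive).
#' @param n Signal length used to clip the upper bound (default
#'   unbounded).
#' @param x_window_fraction Fraction of `cc_mean` searched after C.
#' @return Integer vector `c(lo, hi)` with `lo = c_idx` and
#'   `hi = c_idx + round(x_window_fraction * cc_mean)` (round half up),
#'   clipped to `n`.
#' @export
x_search_interval <- function(c_idx, cc_mean, n = Inf,
                              x_window_fraction = 0.15) {
  if (!is.finite(cc_mean) || cc_mean <= 0)
    stop("cc_mean must be positive")
  hi <- c_idx + floor(x_window_fraction * cc_mean + 0.5)
  c(as.integer(c_idx), as.integer(min(hi, n)))
}

#' X point inside a search interval
#'
#' Takes the first local minimum of the X-detection function strictly
#' inside the interval; when the function is monotone over the interval
#' (no interior local minimum), falls back to the global minimum over
#' the interval excluding the C sample itself.
#'
#' @param cf2 Output of [compute_cf2()].
#' @param interval `c(lo, hi)` from [x_search_interval()].
#' @return Integer index in `(lo, hi]`, or `NA_integer_` for an empty
#'   interval.
#' @export
detect_x_point <- function(cf2, interval) {
  lo <- interval[1L]
  hi <- min(interval[2L], length(cf2))
  if (hi <= lo) return(NA_integer_)
  mn <- find_extrema(cf2)$minima
  mn <- mn[mn > lo & mn < hi]
  if (length(mn)) return(min(mn))
  seg <- (lo + 1L):hi
  seg[which.min(cf2[seg])]
}

#' Per-beat fiducial annotations
#'
#' @param b,c,x Integer vectors of equal length (`NA` allowed in `b` and
#'   `x`): sample indices of the B, C and X points of each beat.
#' @param fs Sampling rate in Hz.
#' @return A data frame of class `icg_fiducials` with columns `beat`,
#'   `b`, `c`, `x` and attribute `fs`. Within each beat `b < c < x`
#'   where present; `c` is strictly increasing across beats.
#' @export
icg_fiducials <- function(b, c, x, fs) {
  stopifnot(length(b) == length(c), length(x) == length(c), fs > 0)
  c <- as.integer(c); b <- as.integer(b); x <- as.integer(x)
  if (anyNA(c)) stop("every beat must have a C point")
  if (length(c) > 1L && is.unsorted(c, strictly = TRUE))
    stop("C indices must be strictly increasing across beats")
  bad <- which(!is.na(b) & b >= c)
  if (length(bad)) stop("beat ", bad[1L], ": B index not before C")
  bad <- which(!is.na(x) & x <= c)
  if (length(bad)) stop("beat ", bad[1L], ": X index not after C")
  structure(data.frame(beat = seq_along(c), b = b, c = c, x = x),
            fs = fs, class = c("icg_fiducials", "data.frame"))
}

#' @export
print.icg_fiducials <- function(x, ...) {
  cat(sprintf("<icg_fiducials> %d beats @ %g Hz (B present: %d, X present: %d)\n",
              nrow(x), attr(x, "fs"), sum(!is.na(x$b)), sum(!is.na(x$x))))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more beats\n")
  invisible(x)
}

#' Detect the B, C and X points of every beat
#'
#' Runs the full delineation pipeline on a preprocessed dZ/dt signal
#' (see [preprocess_icg()]):
#' \enumerate{
#'   \item EMD of the signal; the C-detection function
#'     `cf1 = |(IMF1+...+IMF4) * IMF1*IMF2*IMF3|` is scanned with an
#'     adaptive threshold and a refractory period, and each detection is
#'     snapped onto the dZ/dt maximum.
#'   \item EEMD of the signal; per beat, B is the local maximum of the
#'     derivative of ensemble mode 4 nearest before C, and X is the
#'     first local minimum of `IMF3 + 2 IMF4 + 4 IMF5` within a window
#'     after C sized by the mean beat interval.
#' }
#' B and X may be absent for beats near the record edges; beats without
#' a C point are never emitted.
#'
#' @param signal A preprocessed [icg_signal()].
#' @param sift A [sift_config()].
#' @param ensemble A [ensemble_config()].
#' @param config A [detection_config()].
#' @return An [icg_fiducials()] data frame. The attribute `series` holds
#'   the detector functions (`cf1`, `cf2`, `imf4_deriv`) and
#'   `threshold_state` for inspection.
#' @examples
#' spec <- synth_spec(duration_s = 30, seed = 7)
#' gen <- synth_signal(spec)
#' fid <- detect_fiducials(savgol_smooth(gen$signal))
#' fid
#' @export
detect_fiducials <- function(signal, sift = sift_config(),
                             ensemble = ensemble_config(),
                             config = detection_config()) {
  stopifnot(inherits(signal, "icg_signal"))
  fs <- signal$fs

  dec <- emd(signal, sift)
  if (n_imfs(dec) < 4L)
    stop("EMD produced only ", n_imfs(dec), " IMFs; at least 4 are needed. ",
         "The record may be too short, too smooth or flat.")
  cf1 <- compute_cf1(compute_cf11(dec), compute_cf12(dec))
  train <- detect_c_points(cf1, fs, config)
  c_idx <- train$c_indices
  if (config$snap && length(c_idx)) {
    c_idx <- snap_c_to_signal(c_idx, signal, config$c_snap_window_ms)
    c_idx <- sort(unique(c_idx))
  }
  if (!length(c_idx))
    return(icg_fiducials(integer(0), integer(0), integer(0), fs))

  ens <- eemd(signal, ensemble, sift)
  if (n_imfs(ens) < 4L)
    stop("EEMD produced only ", n_imfs(ens),
         " IMFs; at least 4 are needed for B-point detection")
  d4 <- derivative(ens$imfs[, 4L], fs)
  cf2 <- compute_cf2(ens)

  cc_mean <- if (length(c_idx) >= 2L) compute_cc_mean(c_idx) else NA_real_
  d4_max <- find_extrema(d4)$maxima
  cf2_min <- find_extrema(cf2)$minima
  b_win <- as.integer(round(config$b_search_window_ms * fs / 1000))
  n <- length(signal$samples)

  b <- x <- rep(NA_integer_, length(c_idx))
  for (k in seq_along(c_idx)) {
    ci <- c_idx[k]
    lo_b <- max(ci - b_win, if (k > 1L) c_idx[k - 1L] + 1L else 1L)
    cand_b <- d4_max[d4_max < ci & d4_max >= lo_b]
    if (length(cand_b)) b[k] <- max(cand_b)
    if (is.finite(cc_mean)) {
      iv <- x_search_interval(ci, cc_mean, n, config$x_window_fraction)
      hi <- if (k < length(c_idx)) min(iv[2L], c_idx[k + 1L] - 1L) else iv[2L]
      cand_x <- cf2_min[cf2_min > iv[1L] & cf2_min < hi]
      if (length(cand_x)) {
        x[k] <- min(cand_x)
      } else if (hi > iv[1L] + 1L) {
        seg <- (iv[1L] + 1L):hi
        x[k] <- seg[which.min(cf2[seg])]
      }
    }
  }
  out <- icg_fiducials(b, c_idx, x, fs)
  attr(out, "series") <- list(cf1 = cf1, cf2 = cf2, imf4_deriv = d4,
                              threshold_state = train$threshold_state,
                              cc_mean = cc_mean)
  out
}
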