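#' Construct an ICG signal object
#'
#' A lightweight container for a uniformly sampled real-valued series with
#' its sampling rate. For impedance cardiography the series is the first
#' derivative of the thoracic impedance, dZ/dt, conventionally in Ohm/s.
#'
#' @param samples Numeric vector of samples. Must be finite and of length
#'   at least 2.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param label Optional free-text label carried through processing.
#' @return An object of class `icg_signal`: a list with elements `samples`,
#'   `fs` and `label`.
#' @examples
#' sig <- icg_signal(sin(seq(0, 10, by = 0.004)), fs = 250)
#' sig
#' @export
icg_signal <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("an icg_signal needs at least 2 samples, got ", length(samples))
  if (!all(is.finite(samples)))
    stop("icg_signal samples must all be finite; first bad sample at index ",
         which(!is.finite(samples))[1L])
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(samples = samples, fs = as.numeric(fs),
                 label = as.character(label)[1L]),
            class = "icg_signal")
}

#' @export
print.icg_signal <- function(x, ...) {
  cat(sprintf("<icg_signal> %d samples @ %g Hz (%.2f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.icg_signal <- function(x) length(x$samples)

#' Duration of a signal in seconds
#' @param signal An [icg_signal()].
#' @return Duration in seconds.
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "icg_signal"))
  length(signal$samples) / signal$fs
}

#' Read a signal from a CSV file
#'
#' Reads one numeric column of a comma-separated file with a header row.
#' Any non-numeric or missing value is an error: a silent NA in a
#' physiological record would corrupt every downstream index.
#'
#' @param path Path to an existing CSV file.
#' @param column Name of the column holding the samples.
#' @param fs Sampling rate in Hz of the stored record.
#' @param label Optional label; defaults to the file name.
#' @return An [icg_signal()].
#' @export
read_signal <- function(path, column, fs, label = basename(path)) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("signal file is empty: ", path)
  if (!column %in% names(df))
    stop("column '", column, "' not found in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  v <- df[[column]]
  if (!is.numeric(v)) v <- suppressWarnings(as.numeric(as.character(v)))
  bad <- which(!is.finite(v))
  if (length(bad))
    stop("non-numeric or missing value in column '", column, "' of ", path,
         " at data row ", bad[1L])
  icg_signal(v, fs, label)
}

#' Write a signal to a CSV file
#'
#' @param signal An [icg_signal()].
#' @param path Output path.
#' @param column Column name used in the header.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path, column = "icg") {
  stopifnot(inherits(signal, "icg_signal"))
  df <- data.frame(x = signal$samples)
  names(df) <- column
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Downsample a signal with zero-phase anti-alias filtering
#'
#' Decimates by an integer factor after zero-phase low-pass filtering
#' (FIR filter applied forward and backward), so fiducial timing is
#' preserved with no phase lag. The typical use is reducing a 2000 Hz
#' acquisition to the 250 Hz analysis rate.
#'
#' @param signal An [icg_signal()].
#' @param target_fs Target sampling rate in Hz. Must divide `signal$fs`
#'   into an integer factor and not exceed it (upsampling is out of scope).
#' @return An [icg_signal()] at `target_fs`.
#' @export
resample_signal <- function(signal, target_fs) {
  stopifnot(inherits(signal, "icg_signal"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("target_fs must be a single positive number")
  if (target_fs > signal$fs)
    stop("target_fs (", target_fs, ") exceeds the signal rate (", signal$fs,
         "); upsampling is not supported")
  if (target_fs == signal$fs) return(signal)
  q <- signal$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("decimation factor fs/target_fs = ", signif(q, 6),
         " is not an integer; only integer-factor downsampling is supported")
  q <- as.integer(round(q))
  # cutoff at 80% of the new Nyquist leaves a transition band for the FIR
  h <- as.numeric(signal::fir1(max(64L, 10L * q), 0.8 / q))
  xf <- signal::filtfilt(h, 1, signal$samples)
  icg_signal(xf[seq(1L, length(xf), by = q)], target_fs, signal$label)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing. An order-3 filter reproduces
#' cubic segments exactly, which keeps the sharp systolic upstroke of the
#' dZ/dt waveform intact while suppressing wide-band noise.
#'
#' @param signal An [icg_signal()].
#' @param order Polynomial order (default 3).
#' @param window_samples Odd window length in samples, greater than `order`.
#'   The default 15 spans 60 ms at 250 Hz.
#' @return A smoothed [icg_signal()] of identical length and rate.
#' @export
savgol_smooth <- function(signal, order = 3L, window_samples = 15L) {
  stopifnot(inherits(signal, "icg_signal"))
  if (window_samples %% 2L == 0L)
    stop("window_samples must be odd, got ", window_samples)
  if (window_samples <= order)
    stop("window_samples (", window_samples,
         ") must exceed the polynomial order (", order, ")")
  y <- as.numeric(signal::sgolayfilt(signal$samples, p = order,
                                     n = window_samples))
  icg_signal(y, signal$fs, signal$label)
}

#' Standard ICG preprocessing chain
#'
#' Downsamples to the analysis rate (when needed) and applies
#' Savitzky-Golay smoothing; this is the preprocessing expected by
#' [detect_fiducials()].
#'
#' @param signal An [icg_signal()].
#' @param target_fs Analysis sampling rate (default 250 Hz).
#' @param order,window_samples Savitzky-Golay parameters, see
#'   [savgol_smooth()].
#' @return A preprocessed [icg_signal()].
#' @export
preprocess_icg <- function(signal, target_fs = 250, order = 3L,
                           window_samples = 15L) {
  if (signal$fs > target_fs) signal <- resample_signal(signal, target_fs)
  savgol_smooth(signal, order = order, window_samples = window_samples)
}
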