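#' Sifting configuration for empirical mode decomposition
#'
#' @param sd_threshold Cauchy stopping criterion for the sifting loop:
#'   sifting of one mode stops once
#'   `sum((h_prev - h)^2) / sum(h_prev^2) < sd_threshold`. The default 0.2
#'   is the value in standard use since the original EMD literature.
#' @param max_sift_iters Hard cap on sifting iterations per mode.
#' @param max_imfs Maximum number of intrinsic mode functions to extract.
#' @param boundary_policy End-effect handling for the spline envelopes.
#'   Only `"mirror"` is implemented: the two extrema nearest each record
#'   edge are reflected about the edge before spline fitting, which
#'   suppresses the end swings that would otherwise corrupt fiducial
#'   timing near the record boundaries.
#' @param mean_tol_fraction Tolerance on the "zero envelope mean" IMF
#'   condition: the envelope mean is accepted as zero when its largest
#'   absolute value does not exceed this fraction of the RMS of the
#'   candidate mode.
#' @return A list of class `sift_config`.
#' @export
sift_config <- function(sd_threshold = 0.2, max_sift_iters = 100L,
                        max_imfs = 12L, boundary_policy = c("mirror"),
                        mean_tol_fraction = 0.05) {
  boundary_policy <- match.arg(boundary_policy)
  stopifnot(sd_threshold > 0, max_sift_iters >= 1L, max_imfs >= 1L,
            mean_tol_fraction > 0)
  structure(list(sd_threshold = sd_threshold,
                 max_sift_iters = as.integer(max_sift_iters),
                 max_imfs = as.integer(max_imfs),
                 boundary_policy = boundary_policy,
                 mean_tol_fraction = mean_tol_fraction),
            class = "sift_config")
}

#' Locate strict interior extrema
#'
#' Finds strict local maxima and minima, excluding the first and last
#' sample. A plateau (a run of equal values) that is higher (lower) than
#' both neighbours contributes a single extremum at its midpoint index.
#'
#' @param x Numeric vector, length at least 3.
#' @return A list with integer vectors `maxima` and `minima`, each in
#'   ascending order (possibly empty).
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) stop("find_extrema needs at least 3 samples")
  # compress plateaus to their first index, remember run lengths
  first <- which(c(TRUE, diff(x) != 0))
  runlen <- diff(c(first, n + 1L))
  xs <- x[first]
  m <- length(xs)
  if (m < 3L) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(diff(xs))
  up <- which(s[-(m - 1L)] > 0 & s[-1L] < 0) + 1L
  dn <- which(s[-(m - 1L)] < 0 & s[-1L] > 0) + 1L
  mid <- function(k) as.integer(first[k] + (runlen[k] - 1L) %/% 2L)
  list(maxima = mid(up), minima = mid(dn))
}

#' Count zero crossings
#'
#' Counts sign changes between consecutive samples. A sample that is
#' exactly zero adopts the sign of the following nonzero sample, so a
#' touch of zero without a sign change is not counted as a crossing.
#'
#' @param x Numeric vector, length at least 2.
#' @return Integer crossing count.
#' @export
count_zero_crossings <- function(x) {
  if (length(x) < 2L) stop("count_zero_crossings needs at least 2 samples")
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

insufficient_extrema <- function(n_max, n_min) {
  structure(class = c("icgemd_insufficient_extrema", "error", "condition"),
            list(message = sprintf(
              "signal is monotonic or has too few extrema (%d maxima, %d minima); treating as residual",
              n_max, n_min), call = NULL))
}

# reflect the k extrema nearest each edge about the edge; returns knot
# positions/values for one envelope
mirror_knots <- function(x, idx, n, k = 2L) {
  k <- min(k, length(idx))
  left_pos <- 2L - idx[k:1L]
  left_val <- x[idx[k:1L]]
  right_pos <- 2L * n - idx[length(idx):(length(idx) - k + 1L)]
  right_val <- x[idx[length(idx):(length(idx) - k + 1L)]]
  pos <- c(left_pos, idx, right_pos)
  val <- c(left_val, x[idx], right_val)
  o <- order(pos)
  pos <- pos[o]; val <- val[o]
  keep <- !duplicated(pos)
  list(pos = pos[keep], val = val[keep])
}

#' Cubic-spline envelopes through the extrema
#'
#' Interpolates the upper envelope through the maxima and the lower
#' envelope through the minima with natural cubic splines, after
#' mirror-extending the extrema beyond both record edges.
#'
#' @param x Numeric vector.
#' @param maxima,minima Ascending integer indices of the extrema, e.g.
#'   from [find_extrema()]. At least 2 of each are required.
#' @param boundary_policy Only `"mirror"` is implemented.
#' @return A list with numeric vectors `upper` and `lower`, both of
#'   `length(x)`.
#' @export
compute_envelopes <- function(x, maxima, minima,
                              boundary_policy = "mirror") {
  if (!identical(boundary_policy, "mirror"))
    stop("unknown boundary policy: ", boundary_policy)
  if (length(maxima) < 2L || length(minima) < 2L)
    stop(insufficient_extrema(length(maxima), length(minima)))
  n <- length(x)
  ku <- mirror_knots(x, maxima, n)
  kl <- mirror_knots(x, minima, n)
  at <- seq_len(n)
  list(upper = stats::splinefun(ku$pos, ku$val, method = "natural")(at),
       lower = stats::splinefun(kl$pos, kl$val, method = "natural")(at))
}

#' Mean of the upper and lower envelopes
#'
#' @param upper,lower Numeric vectors of equal length.
#' @return Elementwise `(upper + lower) / 2`.
#' @export
envelope_mean <- function(upper, lower) {
  if (length(upper) != length(lower))
    stop("envelope length mismatch: ", length(upper), " vs ", length(lower))
  (upper + lower) / 2
}

#' Test whether a series is an intrinsic mode function
#'
#' A series qualifies as an IMF when (i) its number of extrema and its
#' number of zero crossings differ by at most one, and (ii) the mean of
#' its spline envelopes is zero everywhere, within a tolerance expressed
#' as a fraction of the series RMS.
#'
#' @param h Numeric vector, length at least 3.
#' @param mean_tol_fraction Envelope-mean tolerance (see [sift_config()]).
#' @return `TRUE` or `FALSE`. Series with fewer than two maxima or two
#'   minima (so that no envelope exists) are not IMFs.
#' @export
is_imf <- function(h, mean_tol_fraction = 0.05) {
  e <- find_extrema(h)
  if (length(e$maxima) < 2L || length(e$minima) < 2L) return(FALSE)
  n_ext <- length(e$maxima) + length(e$minima)
  n_zc <- count_zero_crossings(h)
  if (abs(n_ext - n_zc) > 1L) return(FALSE)
  env <- compute_envelopes(h, e$maxima, e$minima)
  m <- envelope_mean(env$upper, env$lower)
  max(abs(m)) <= mean_tol_fraction * sqrt(mean(h^2))
}

#' Sift one intrinsic mode function out of a series
#'
#' Repeatedly subtracts the envelope mean. Sifting of the mode stops as
#' soon as one of these holds, in order of preference:
#' \describe{
#'   \item{`"imf"`}{the candidate passes the full [is_imf()] test;}
#'   \item{`"sd"`}{the Cauchy criterion
#'     `sum((h_prev - h)^2) / sum(h_prev^2)` has dropped below
#'     `sd_threshold` (the envelope mean is then small in the
#'     mean-square sense, though not necessarily within the strict
#'     pointwise [is_imf()] tolerance);}
#'   \item{`"max_iters"`}{the iteration cap was reached.}
#' }
#'
#' @param x Numeric vector with at least two maxima and two minima.
#' @param config A [sift_config()].
#' @return A list with `imf` (numeric vector), `iterations` (integer
#'   >= 1), `stop_reason` (one of `"imf"`, `"sd"`, `"max_iters"`) and
#'   `converged` (`TRUE` unless the cap was hit).
#' @export
extract_imf <- function(x, config = sift_config()) {
  h <- x
  for (it in seq_len(config$max_sift_iters)) {
    e <- find_extrema(h)
    if (length(e$maxima) < 2L || length(e$minima) < 2L)
      stop(insufficient_extrema(length(e$maxima), length(e$minima)))
    env <- compute_envelopes(h, e$maxima, e$minima, config$boundary_policy)
    m <- envelope_mean(env$upper, env$lower)
    h1 <- h - m
    sd_k <- sum(m^2) / sum(h^2)
    if (is_imf(h1, config$mean_tol_fraction))
      return(list(imf = h1, iterations = it, stop_reason = "imf",
                  converged = TRUE))
    if (sd_k < config$sd_threshold)
      return(list(imf = h1, iterations = it, stop_reason = "sd",
                  converged = TRUE))
    h <- h1
  }
  list(imf = h, iterations = config$max_sift_iters,
       stop_reason = "max_iters", converged = FALSE)
}

new_imf_set <- function(imfs, residual, method, fs) {
  structure(list(imfs = imfs, residual = residual, method = method,
                 fs = fs), class = "imf_set")
}

#' Number of intrinsic mode functions in a decomposition
#' @param x An `imf_set`.
#' @return Integer count of IMFs (the residual is not counted).
#' @export
n_imfs <- function(x) {
  stopifnot(inherits(x, "imf_set"))
  if (is.null(x$imfs)) 0L else ncol(x$imfs)
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %s: %d IMFs + residual, %d samples%s\n",
              toupper(x$method), n_imfs(x),
              length(x$residual),
              if (is.finite(x$fs)) sprintf(" @ %g Hz", x$fs) else ""))
  invisible(x)
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions plus a residual,
#' `x = sum(IMF_i) + r`, by iterative sifting with cubic-spline
#' envelopes. Decomposition stops when the residual is constant,
#' monotonic, or has too few extrema to support an envelope, or when
#' `max_imfs` modes have been extracted. Reconstruction is exact by
#' construction: modes are obtained by subtraction only.
#'
#' @param x Numeric vector (length >= 4) or an [icg_signal()].
#' @param config A [sift_config()].
#' @param fs Sampling rate metadata when `x` is a plain vector; taken
#'   from the signal otherwise.
#' @return An object of class `imf_set`: list with `imfs` (matrix, one
#'   column per IMF; `NULL` when none), `residual`, `method = "emd"` and
#'   `fs`. The attribute `sift_log` records, per mode, the number of
#'   sifting iterations, the stopping reason (see [extract_imf()]) and a
#'   convergence flag.
#' @examples
#' t <- seq(0, 2, by = 1 / 250)
#' d <- emd(sin(2 * pi * 10 * t) + sin(2 * pi * 1 * t), fs = 250)
#' n_imfs(d)
#' @export
emd <- function(x, config = sift_config(), fs = NA_real_) {
  if (inherits(x, "icg_signal")) {
    fs <- x$fs
    x <- x$samples
  }
  x <- as.numeric(x)
  if (length(x) < 4L) stop("emd needs at least 4 samples")
  r <- x
  imfs <- list()
  iters <- integer(0)
  reason <- character(0)
  while (length(imfs) < config$max_imfs) {
    e <- find_extrema(r)
    if (length(e$maxima) < 2L || length(e$minima) < 2L) break
    s <- tryCatch(extract_imf(r, config),
                  icgemd_insufficient_extrema = function(e) NULL)
    if (is.null(s)) break  # candidate degenerated mid-sift: r is the residual
    imfs[[length(imfs) + 1L]] <- s$imf
    iters <- c(iters, s$iterations)
    reason <- c(reason, s$stop_reason)
    r <- r - s$imf
  }
  out <- new_imf_set(if (length(imfs)) do.call(cbind, imfs) else NULL,
                     r, "emd", fs)
  attr(out, "sift_log") <- data.frame(imf = seq_along(iters),
                                      iterations = iters,
                                      stop_reason = reason,
                                      converged = reason != "max_iters")
  out
}

#' Write a decomposition to CSV
#'
#' One column per IMF (named `imf1`, `imf2`, ...) and a final `residual`
#' column.
#'
#' @param imfset An `imf_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imfs <- function(imfset, path) {
  stopifnot(inherits(imfset, "imf_set"))
  k <- n_imfs(imfset)
  df <- as.data.frame(if (k) imfset$imfs else
                        matrix(numeric(0), length(imfset$residual), 0))
  if (k) names(df) <- paste0("imf", seq_len(k))
  df$residual <- imfset$residual
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
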