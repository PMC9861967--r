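#' Ensemble configuration for EEMD
#'
#' @param n_realizations Number of noise realizations averaged (Nt).
#' @param noise_fraction Standard deviation of the added white Gaussian
#'   noise, as a fraction of the standard deviation of the input series.
#' @param seed Master seed. Each realization draws its noise from an
#'   independent substream derived from this seed and the realization
#'   index, so results do not depend on evaluation order.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_realizations = 100L, noise_fraction = 0.2,
                            seed = 1L) {
  stopifnot(n_realizations >= 1L, noise_fraction >= 0)
  structure(list(n_realizations = as.integer(n_realizations),
                 noise_fraction = noise_fraction,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

# substream seed for realization i, kept inside 32-bit integer range
realization_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}

# run expr with a local RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Add white Gaussian noise to a series
#'
#' @param x Numeric vector.
#' @param noise_fraction Noise standard deviation as a fraction of
#'   `sd(x)`.
#' @param seed Integer seed; the same seed always yields the same noise.
#' @return `x` plus the noise (identical to `x` when `noise_fraction`
#'   is 0).
#' @export
add_white_noise <- function(x, noise_fraction, seed) {
  stopifnot(noise_fraction >= 0)
  if (noise_fraction == 0) return(x)
  amp <- noise_fraction * stats::sd(x)
  x + with_local_seed(seed, stats::rnorm(length(x), 0, amp))
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `n_realizations` copies of the input, each perturbed
#' with an independent white-noise draw, and averages the modes order by
#' order. Realizations that yield fewer modes than the deepest one
#' contribute zeros for the missing high orders, keeping the mode-wise
#' mean well defined. Averaging breaks the exact-IMF property of the
#' individual modes (a known feature of EEMD), but the sum of the
#' averaged modes plus the averaged residual still equals the ensemble
#' mean of the noisy inputs.
#'
#' With `noise_fraction = 0` every realization is identical, so the
#' result equals the plain EMD of `x` for any ensemble size.
#'
#' @param x Numeric vector or an [icg_signal()].
#' @param ensemble A [ensemble_config()].
#' @param config A [sift_config()].
#' @param fs Sampling rate metadata when `x` is a plain vector.
#' @return An `imf_set` with `method = "eemd"`.
#' @export
eemd <- function(x, ensemble = ensemble_config(), config = sift_config(),
                 fs = NA_real_) {
  if (inherits(x, "icg_signal")) {
    fs <- x$fs
    x <- x$samples
  }
  x <- as.numeric(x)
  if (length(x) < 4L) stop("eemd needs at least 4 samples")

  if (ensemble$noise_fraction == 0) {
    # all realizations coincide with the unperturbed series
    base <- emd(x, config, fs)
    out <- new_imf_set(base$imfs, base$residual, "eemd", fs)
    attr(out, "sift_log") <- attr(base, "sift_log")
    return(out)
  }

  n <- length(x)
  nt <- ensemble$n_realizations
  runs <- vector("list", nt)
  kmax <- 0L
  for (i in seq_len(nt)) {
    xi <- add_white_noise(x, ensemble$noise_fraction,
                          realization_seed(ensemble$seed, i))
    runs[[i]] <- emd(xi, config, fs)
    kmax <- max(kmax, n_imfs(runs[[i]]))
  }
  acc <- matrix(0, n, kmax)
  res <- numeric(n)
  for (i in seq_len(nt)) {
    k <- n_imfs(runs[[i]])
    if (k) acc[, seq_len(k)] <- acc[, seq_len(k)] + runs[[i]]$imfs
    res <- res + runs[[i]]$residual
  }
  new_imf_set(if (kmax) acc / nt else NULL, res / nt, "eemd", fs)
}
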