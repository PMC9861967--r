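# two-decimal rounding, ties away from zero (printed-accuracy convention)
round2_half_up <- function(x) floor(x * 100 + 0.5) / 100

#' Match detected points to reference annotations within a tolerance
#'
#' Greedy one-to-one matching: references are visited in ascending
#' order and each takes its nearest unused detected point, provided the
#' distance does not exceed the tolerance (ties go to the earlier
#' detected index). On well-separated annotation trains (spacing larger
#' than twice the tolerance, as in beat-to-beat data) this equals the
#' optimal bipartite matching.
#'
#' @param detected,reference Ascending integer sample indices.
#' @param tolerance_samples Maximum allowed |detected - reference|
#'   (default 7 samples, i.e. 28 ms at 250 Hz, within the conventional
#'   30 ms agreement tolerance).
#' @param fs Optional sampling rate used only to report the tolerance
#'   in ms.
#' @return A list of class `match_result`: `n_matched`, `n_reference`,
#'   `n_detected`, `tolerance_samples`, `tolerance_ms` (`NA` without
#'   `fs`), `errors_samples` (signed detected - reference for matched
#'   pairs, in reference order) and `accuracy_pct` (percentage of
#'   references matched, two decimals).
#' @export
match_points <- function(detected, reference, tolerance_samples = 7L,
                         fs = NULL) {
  detected <- as.integer(detected[!is.na(detected)])
  reference <- as.integer(reference[!is.na(reference)])
  if (is.unsorted(detected)) stop("detected indices must be ascending")
  if (is.unsorted(reference)) stop("reference indices must be ascending")
  stopifnot(tolerance_samples >= 0)
  used <- logical(length(detected))
  errors <- integer(0)
  n_matched <- 0L
  for (r in reference) {
    if (!length(detected)) break
    d <- abs(detected - r)
    d[used] <- NA
    j <- which.min(d)  # earliest index on ties
    if (length(j) && !is.na(d[j]) && d[j] <= tolerance_samples) {
      used[j] <- TRUE
      n_matched <- n_matched + 1L
      errors <- c(errors, detected[j] - r)
    }
  }
  structure(list(n_matched = n_matched,
                 n_reference = length(reference),
                 n_detected = length(detected),
                 tolerance_samples = as.integer(tolerance_samples),
                 tolerance_ms = if (is.null(fs)) NA_real_
                                else 1000 * tolerance_samples / fs,
                 errors_samples = errors,
                 accuracy_pct = if (length(reference))
                   percentage_accuracy(n_matched, length(reference))
                   else NA_real_),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d/%d reference points matched (%d detected) within %d samples%s: %.2f%%\n",
    x$n_matched, x$n_reference, x$n_detected, x$tolerance_samples,
    if (is.finite(x$tolerance_ms)) sprintf(" (%g ms)", x$tolerance_ms)
    else "", x$accuracy_pct))
  invisible(x)
}

#' Percentage accuracy of a point detector
#'
#' @param n_matched Number of reference points matched.
#' @param n_reference Total number of reference points (positive).
#' @return `100 * n_matched / n_reference`, rounded to two decimals
#'   (ties rounded up).
#' @examples
#' percentage_accuracy(584, 623)  # 93.74
#' @export
percentage_accuracy <- function(n_matched, n_reference) {
  if (n_reference <= 0) stop("n_reference must be positive")
  if (n_matched < 0 || n_matched > n_reference)
    stop("n_matched must lie in [0, n_reference]")
  round2_half_up(100 * n_matched / n_reference)
}

#' Difference of medians between two estimators
#'
#' @param algorithm_values,expert_values Nonempty numeric vectors of
#'   the same quantity as estimated by the algorithm and the reference
#'   annotator.
#' @return `median(algorithm_values) - median(expert_values)`.
#' @export
median_difference <- function(algorithm_values, expert_values) {
  if (!length(algorithm_values) || !length(expert_values))
    stop("both inputs must be nonempty")
  stats::median(algorithm_values) - stats::median(expert_values)
}

#' Evaluate a detected annotation set against a reference
#'
#' Matches the B, C and X trains separately and reports a per-point
#' accuracy block.
#'
#' @param detected,reference [icg_fiducials()] annotation sets on the
#'   same record.
#' @param tolerance_samples Matching tolerance (default 7 samples).
#' @return A list of class `fiducial_evaluation` with one
#'   [match_points()] result per point type (`b`, `c`, `x`) and the
#'   tolerance in ms.
#' @export
evaluate_fiducials <- function(detected, reference,
                               tolerance_samples = 7L) {
  stopifnot(inherits(detected, "icg_fiducials"),
            inherits(reference, "icg_fiducials"))
  fs <- attr(reference, "fs")
  res <- lapply(c(b = "b", c = "c", x = "x"), function(p)
    match_points(sort(detected[[p]][!is.na(detected[[p]])]),
                 sort(reference[[p]][!is.na(reference[[p]])]),
                 tolerance_samples, fs = fs))
  structure(c(res, list(tolerance_samples = as.integer(tolerance_samples),
                        tolerance_ms = 1000 * tolerance_samples / fs)),
            class = "fiducial_evaluation")
}

#' @export
print.fiducial_evaluation <- function(x, ...) {
  cat(sprintf("<fiducial_evaluation> tolerance %d samples (%g ms)\n",
              x$tolerance_samples, x$tolerance_ms))
  for (p in c("b", "c", "x"))
    cat(sprintf("  %s: %6.2f%% (%d/%d)\n", toupper(p), x[[p]]$accuracy_pct,
                x[[p]]$n_matched, x[[p]]$n_reference))
  invisible(x)
}
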