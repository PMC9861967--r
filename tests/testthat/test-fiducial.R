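make_imfset <- function(imfs, fs = 250, method = "emd") {
  icgemd:::new_imf_set(imfs, residual = numeric(nrow(imfs)),
                       method = method, fs = fs)
}

test_that("detector functions equal their brute-force definitions", {
  set.seed(21)
  m <- matrix(rnorm(600), ncol = 6)
  s <- make_imfset(m)
  expect_equal(compute_cf11(s), m[, 1] + m[, 2] + m[, 3] + m[, 4])
  expect_equal(compute_cf12(s), m[, 1] * m[, 2] * m[, 3])
  cf11 <- compute_cf11(s); cf12 <- compute_cf12(s)
  expect_equal(compute_cf1(cf11, cf12), abs(cf11 * cf12))
  expect_true(all(compute_cf1(cf11, cf12) >= 0))
  expect_equal(compute_cf2(s), m[, 3] + 2 * m[, 4] + 4 * m[, 5])

  expect_equal(compute_cf11(make_imfset(matrix(1, 5, 4))), rep(4, 5))
  expect_equal(compute_cf12(make_imfset(
    matrix(rep(c(2, 3, 5), each = 4), ncol = 3))), rep(30, 4))
  expect_error(compute_cf11(make_imfset(m[, 1:3])), "at least 4")
  expect_error(compute_cf12(make_imfset(m[, 1:2, drop = FALSE])),
               "at least 3")
  expect_error(compute_cf1(1:3, 1:4), "mismatch")
  # missing fifth mode is padded with zeros, with a warning
  expect_warning(cf2_4 <- compute_cf2(make_imfset(matrix(1, 6, 4))),
                 "zero")
  expect_equal(cf2_4, rep(3, 6))
})

gauss_bump_train <- function(centers, n, width = 4, amp = 1) {
  if (length(amp) == 1) amp <- rep(amp, length(centers))
  x <- numeric(n)
  for (k in seq_along(centers))
    x <- x + amp[k] * exp(-0.5 * ((seq_len(n) - centers[k]) / width)^2)
  x
}

test_that("detect_c_points finds isolated bumps at their apex", {
  n <- 2500
  x <- gauss_bump_train(1250, n)
  tr <- detect_c_points(x, fs = 250)
  expect_equal(tr$c_indices, 1250L)
  expect_true(is.na(tr$cc_mean))

  # two equal bumps 100 ms apart (inside the 200 ms refractory):
  # a single detection at the first bump
  x2 <- gauss_bump_train(c(1250, 1275), n)
  tr2 <- detect_c_points(x2, fs = 250)
  expect_equal(length(tr2$c_indices), 1L)
  expect_equal(tr2$c_indices, 1250L)

  expect_equal(detect_c_points(numeric(100), 250)$c_indices, integer(0))
})

test_that("a noisy bump train is detected almost completely", {
  set.seed(31)
  fs <- 250
  centers <- round(cumsum(c(300, rnorm(59, 200, 10))))  # ~0.8 s spacing
  n <- max(centers) + 300
  clean <- gauss_bump_train(centers, n, amp = rnorm(60, 1, 0.07))
  noise_sd <- sqrt(mean(clean^2)) / 10  # 20 dB
  x <- abs(clean + rnorm(n, 0, noise_sd))
  det <- detect_c_points(x, fs)$c_indices
  hits <- vapply(centers, function(cc) any(abs(det - cc) <= 2), logical(1))
  expect_gte(sum(hits), 59L)
})

test_that("no two detections violate the refractory period", {
  set.seed(32)
  for (i in 1:5) {
    x <- abs(rnorm(3000)) * rbinom(3000, 1, 0.02)
    det <- detect_c_points(x, fs = 250)$c_indices
    if (length(det) >= 2) expect_gte(min(diff(det)), 50L)
  }
})

test_that("snap_c_to_signal moves detections onto the signal maximum", {
  sig <- icg_signal(gauss_bump_train(100, 300), 250)
  expect_equal(snap_c_to_signal(100L, sig), 100L)
  expect_equal(snap_c_to_signal(97L, sig), 100L)   # 3 samples off, +-10 win
  expect_equal(snap_c_to_signal(97L, sig, window_ms = 0), 97L)
  expect_error(snap_c_to_signal(1000L, sig), "outside")
})

test_that("compute_cc_mean averages consecutive gaps", {
  expect_equal(compute_cc_mean(c(1, 201, 401)), 200)
  expect_equal(compute_cc_mean(c(1, 101, 301)), 150)
  set.seed(33)
  idx <- cumsum(sample(50:100, 20, replace = TRUE))
  expect_equal(compute_cc_mean(idx), mean(diff(idx)))
  expect_error(compute_cc_mean(5), "at least 2")
  expect_error(compute_cc_mean(c(5, 5)), "increasing")
})

test_that("derivative matches analytic slopes", {
  fs <- 250
  x <- seq_len(100) * 0.4
  d <- derivative(x, fs)
  expect_equal(d[2:99], rep(0.4 * fs, 98))
  expect_equal(derivative(rep(3, 50), fs), rep(0, 50))

  f <- 5
  t <- seq(0, 2, by = 1 / fs)
  d2 <- derivative(sin(2 * pi * f * t), fs)
  truth <- 2 * pi * f * cos(2 * pi * f * t)
  idx <- interior(length(t), 0.9)
  expect_lt(max(abs(d2[idx] - truth[idx])), (2 * pi * f / fs)^2 * 2 * pi * f)
})

test_that("detect_b_point takes the derivative maximum nearest before C", {
  fs <- 250
  # derivative has a single local max 20 samples before c_idx = 500
  d4 <- gauss_bump_train(480, 1000)
  b <- detect_b_point(d4, 500L, fs, is_derivative = TRUE)
  expect_equal(b, 480L)
  # nothing in the window -> absent
  expect_true(is.na(detect_b_point(d4, 700L, fs, is_derivative = TRUE)))
  # integrated bump: the derivative of cumsum recovers the bump apex
  # (one-sample discretisation slack)
  b2 <- detect_b_point(cumsum(d4) / fs, 500L, fs)
  expect_lte(abs(b2 - 480L), 1L)
})

test_that("x_search_interval applies the beat-fraction bound", {
  expect_equal(x_search_interval(1000L, 200), c(1000L, 1030L))
  expect_equal(x_search_interval(1000L, 210), c(1000L, 1032L))
  expect_equal(x_search_interval(1000L, 200, n = 1010), c(1000L, 1010L))
  expect_error(x_search_interval(1000L, 0), "positive")
})

test_that("detect_x_point prefers interior minima, falls back to the global one", {
  v <- c(rep(5, 10), 5:1, 1:5, rep(5, 10))  # trough at index 15
  expect_equal(detect_x_point(v, c(10L, 25L)), 15L)
  mono <- seq(30, 1)
  expect_equal(detect_x_point(mono, c(5L, 20L)), 20L)
  expect_true(is.na(detect_x_point(mono, c(5L, 5L))))
})

test_that("the full pipeline recovers a clean synthetic record", {
  gen <- synth_signal(synth_spec(duration_s = 30, noise_sd = 0,
                                 wander_amplitude = 0, seed = 101))
  fid <- detect_fiducials(savgol_smooth(gen$signal),
                          ensemble = ensemble_config(n_realizations = 20,
                                                     seed = 101))
  ref <- gen$annotations
  expect_equal(nrow(fid), nrow(ref))
  expect_true(all(abs(fid$c - ref$c) <= 2))
  # output ordering invariants
  ok_b <- !is.na(fid$b)
  ok_x <- !is.na(fid$x)
  expect_true(all(fid$b[ok_b] < fid$c[ok_b]))
  expect_true(all(fid$x[ok_x] > fid$c[ok_x]))
  expect_true(!is.unsorted(fid$c, strictly = TRUE))
})

test_that("detection is deterministic under fixed seeds", {
  gen <- synth_signal(synth_spec(duration_s = 20, snr_db = 20, seed = 55))
  sig <- savgol_smooth(gen$signal)
  ens <- ensemble_config(n_realizations = 10, seed = 55)
  f1 <- detect_fiducials(sig, ensemble = ens)
  f2 <- detect_fiducials(sig, ensemble = ens)
  expect_identical(f1$b, f2$b)
  expect_identical(f1$c, f2$c)
  expect_identical(f1$x, f2$x)
})

test_that("degenerate inputs are rejected with guidance", {
  flat <- icg_signal(rep(1, 1000) + c(0, 1e-12, 0, rep(0, 997)), 250)
  expect_error(detect_fiducials(flat), "IMF")
})

test_that("fiducial annotations enforce ordering invariants", {
  expect_error(icg_fiducials(b = 5L, c = 4L, x = 10L, fs = 250), "before C")
  expect_error(icg_fiducials(b = 1L, c = 4L, x = 3L, fs = 250), "after C")
  expect_error(icg_fiducials(b = c(1L, 20L), c = c(10L, 5L),
                             x = c(12L, 30L), fs = 250), "increasing")
  fid <- icg_fiducials(b = c(1L, NA), c = c(5L, 50L), x = c(9L, NA),
                       fs = 250)
  expect_s3_class(fid, "icg_fiducials")
  expect_equal(attr(fid, "fs"), 250)
})
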