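test_that("find_extrema matches a brute-force scan, with plateau rule", {
  expect_equal(find_extrema(c(0, 1, 0, -1, 0)),
               list(maxima = 1L + 1L, minima = 3L + 1L) |>
                 setNames(c("maxima", "minima")))
  expect_equal(find_extrema(seq_len(10)),
               list(maxima = integer(0), minima = integer(0)))
  # plateau maximum contributes its midpoint once
  expect_equal(find_extrema(c(0, 1, 1, 1, 0))$maxima, 3L)
  expect_equal(find_extrema(c(0, 1, 1, 0))$maxima, 2L)

  t <- seq(0, 3, length.out = 1000)
  x <- sin(2 * pi * t)
  expect_equal(find_extrema(x), brute_extrema(x))

  set.seed(5)
  for (i in 1:20) {
    y <- round(rnorm(60), 1)  # rounding forces frequent plateaus
    expect_equal(find_extrema(y), brute_extrema(y))
  }
})

test_that("count_zero_crossings follows the exact-zero convention", {
  expect_equal(count_zero_crossings(c(1, -1, 1)), 2L)
  expect_equal(count_zero_crossings(abs(rnorm(10)) + 0.1), 0L)
  expect_equal(count_zero_crossings(c(1, 0, -1)), 1L)
  expect_equal(count_zero_crossings(c(1, 0, 1)), 0L)
  expect_equal(count_zero_crossings(c(0, 1, -1)), 1L)

  t <- seq(0, 3, length.out = 1000)
  x <- sin(2 * pi * t)
  expect_equal(count_zero_crossings(x), brute_zero_crossings(x))
  set.seed(6)
  for (i in 1:20) {
    y <- round(rnorm(50), 1)
    expect_equal(count_zero_crossings(y), brute_zero_crossings(y))
  }
})

test_that("compute_envelopes interpolates through the extrema", {
  # equal maxima -> constant upper envelope between knots
  t <- seq(0, 6 * pi, length.out = 600)
  x <- sin(t)
  e <- find_extrema(x)
  env <- compute_envelopes(x, e$maxima, e$minima)
  expect_equal(env$upper[e$maxima], x[e$maxima])
  expect_equal(env$lower[e$minima], x[e$minima])
  idx <- interior(length(x), 0.8)
  expect_lt(max(abs(env$upper[idx] - 1)), 0.05)
  m <- envelope_mean(env$upper, env$lower)
  expect_lt(max(abs(m[idx])), 0.05)

  expect_error(compute_envelopes(x, e$maxima[1], e$minima),
               class = "icgemd_insufficient_extrema")

  # two maxima only: spline through two knots (plus mirrored copies)
  y <- c(0, 2, 0, 2, 0)
  env2 <- compute_envelopes(y, c(2L, 4L), c(1L, 3L))
  expect_equal(env2$upper[c(2, 4)], c(2, 2))
})

test_that("envelope_mean is the elementwise mean", {
  expect_equal(envelope_mean(c(2, 2), c(0, 0)), c(1, 1))
  u <- rnorm(30); l <- rnorm(30)
  expect_equal(envelope_mean(u, l), (u + l) / 2)
  expect_error(envelope_mean(1:3, 1:4), "mismatch")
})

test_that("is_imf accepts oscillatory zero-mean series and rejects others", {
  t <- seq(0, 5, length.out = 1250)
  expect_true(is_imf(sin(2 * pi * t)))
  expect_false(is_imf(seq(0, 1, length.out = 100)))
  expect_false(is_imf(sin(2 * pi * t) + 0.5))
})

test_that("extract_imf sifts a clean tone out quickly", {
  t <- seq(0, 5, length.out = 1250)
  x <- sin(2 * pi * 2 * t)
  s <- extract_imf(x)
  expect_true(s$converged)
  expect_lte(s$iterations, 5L)
  idx <- interior(length(x), 0.8)
  expect_gt(stats::cor(s$imf[idx], x[idx]), 0.999)

  expect_error(extract_imf(rep(1, 100)),
               class = "icgemd_insufficient_extrema")
})

test_that("emd reconstructs its input exactly and yields valid modes", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(256:1024, 1)
    x <- as.numeric(stats::filter(rnorm(n), rep(1 / 4, 4), sides = 1))
    x[is.na(x)] <- 0
    d <- emd(x)
    recon <- (if (n_imfs(d)) rowSums(d$imfs) else 0) + d$residual
    expect_lt(max(abs(x - recon)), 1e-9 * max(abs(x)))
    log <- attr(d, "sift_log")
    for (k in seq_len(n_imfs(d))) {
      # the log's stopping reason is truthful
      if (log$stop_reason[k] == "imf") expect_true(is_imf(d$imfs[, k]))
    }
  }
})

test_that("emd separates a fast and a slow tone into leading modes", {
  tt <- two_tone()
  d <- emd(tt$x, fs = 250)
  expect_gte(n_imfs(d), 2L)
  idx <- interior(length(tt$x), 0.8)
  expect_gt(stats::cor(d$imfs[idx, 1], tt$fast[idx]), 0.95)
  expect_gt(stats::cor(d$imfs[idx, 2], tt$slow[idx]), 0.95)
})

test_that("emd of a monotone ramp returns no modes", {
  x <- seq(0, 5, length.out = 200)
  d <- emd(x)
  expect_equal(n_imfs(d), 0L)
  expect_equal(d$residual, x)
})

test_that("emd commutes with scaling", {
  set.seed(12)
  x <- cumsum(rnorm(512))
  d1 <- emd(x)
  d2 <- emd(3.5 * x)
  expect_equal(n_imfs(d1), n_imfs(d2))
  expect_lt(max(abs(3.5 * d1$imfs - d2$imfs)), 1e-9 * max(abs(x)))
})

test_that("an IMF set serializes to CSV with one column per mode", {
  d <- emd(two_tone(duration = 4)$x, fs = 250)
  path <- withr::local_tempfile(fileext = ".csv")
  write_imfs(d, path)
  back <- utils::read.csv(path)
  expect_equal(ncol(back), n_imfs(d) + 1L)
  expect_equal(back$residual, d$residual)
  expect_equal(back$imf1, d$imfs[, 1])
})
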