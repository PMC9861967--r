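test_that("match_points pairs annotations one-to-one within tolerance", {
  ref <- as.integer(seq(100, 5000, by = 100))
  m <- match_points(ref, ref)
  expect_equal(m$n_matched, length(ref))
  expect_equal(m$accuracy_pct, 100.00)
  expect_equal(m$errors_samples, rep(0L, length(ref)))

  # one sample beyond the tolerance: nothing matches
  m8 <- match_points(ref + 8L, ref, tolerance_samples = 7)
  expect_equal(m8$n_matched, 0L)
  expect_equal(m8$accuracy_pct, 0.00)

  # known jitter is recovered exactly as the signed error list
  set.seed(51)
  jit <- sample(-5:5, 50, replace = TRUE)
  ref50 <- as.integer(seq(100, by = 100, length.out = 50))
  m_j <- match_points(ref50 + jit, ref50)
  expect_equal(m_j$n_matched, 50L)
  expect_equal(m_j$errors_samples, jit)

  expect_error(match_points(c(5L, 1L), ref), "ascending")
  expect_error(match_points(ref, c(5L, 1L)), "ascending")
})

test_that("matching is count-symmetric and monotone in tolerance", {
  set.seed(52)
  for (i in 1:10) {
    ref <- cumsum(sample(20:60, 30, replace = TRUE))
    det <- ref + sample(-9:9, 30, replace = TRUE)
    det <- sort(det[runif(30) < 0.9])
    a <- match_points(det, ref)$n_matched
    b <- match_points(ref, det)$n_matched
    expect_equal(a, b)
    accs <- vapply(c(0, 2, 5, 7, 9), function(tol)
      match_points(det, ref, tol)$accuracy_pct, numeric(1))
    expect_true(all(diff(accs) >= 0))
  }
})

test_that("greedy matching is optimal on well-separated trains", {
  set.seed(53)
  for (i in 1:10) {
    ref <- cumsum(sample(16:40, 40, replace = TRUE))  # spacing > 2 * tol
    det <- sort(ref + sample(-8:8, 40, replace = TRUE))
    m <- match_points(det, ref, tolerance_samples = 7)
    expect_equal(m$n_matched, brute_match_count_spaced(det, ref, 7))
  }
})

test_that("percentage accuracy rounds to two decimals half-up", {
  expect_equal(percentage_accuracy(584, 623), 93.74)
  expect_equal(percentage_accuracy(610, 623), 97.91)
  expect_equal(percentage_accuracy(519, 623), 83.31)
  expect_equal(percentage_accuracy(0, 10), 0.00)
  expect_equal(percentage_accuracy(1, 3), 33.33)
  expect_equal(percentage_accuracy(2, 3), 66.67)
  # exact .xx5 ties round up
  expect_equal(percentage_accuracy(1, 8000) , 0.01)  # 0.0125
  expect_equal(percentage_accuracy(3, 8000), 0.04)   # 0.0375
  expect_error(percentage_accuracy(5, 0), "positive")
  expect_error(percentage_accuracy(7, 5), "n_matched")
})

test_that("median_difference subtracts the reference median", {
  expect_equal(median_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(54)
  a <- rnorm(31); b <- rnorm(45)
  expect_equal(median_difference(a, b),
               sort(a)[16] - (sort(b)[23]))
  expect_error(median_difference(numeric(0), 1), "nonempty")
})

test_that("evaluate_fiducials reports per-point accuracy with ms tolerance", {
  fs <- 250
  ref <- icg_fiducials(b = c(90L, 290L), c = c(100L, 300L),
                       x = c(130L, 330L), fs = fs)
  det <- icg_fiducials(b = c(95L, 285L), c = c(101L, 300L),
                       x = c(130L, 345L), fs = fs)
  ev <- evaluate_fiducials(det, ref)
  expect_equal(ev$tolerance_ms, 28)
  expect_equal(ev$c$accuracy_pct, 100.00)
  expect_equal(ev$b$accuracy_pct, 100.00)
  expect_equal(ev$x$accuracy_pct, 50.00)
})

test_that("annotations survive the CSV and JSON round trips", {
  fid <- icg_fiducials(b = c(10L, NA, 110L), c = c(20L, 70L, 120L),
                       x = c(30L, 80L, NA), fs = 250)
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_annotations(fid, path)
    back <- read_annotations(path, fs = 250)
    expect_equal(back$b, fid$b)
    expect_equal(back$c, fid$c)
    expect_equal(back$x, fid$x)
  }
})
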