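# Brute-force reference implementations, deliberately slow and simple,
# used as independent oracles for the vectorized package code.

# strict interior extrema with plateau-midpoint convention, by direct scan
brute_extrema <- function(x) {
  n <- length(x)
  maxima <- integer(0)
  minima <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L  # plateau i..j
    if (i > 1L && j < n) {
      left <- x[i - 1L]
      right <- x[j + 1L]
      mid <- as.integer(i + (j - i) %/% 2L)
      if (left < x[i] && right < x[i]) maxima <- c(maxima, mid)
      if (left > x[i] && right > x[i]) minima <- c(minima, mid)
    }
    i <- j + 1L
  }
  list(maxima = maxima, minima = minima)
}

# zero crossings with exact zeros adopting the following sample's sign
brute_zero_crossings <- function(x) {
  s <- sign(x)
  for (i in rev(seq_len(length(s) - 1L)))
    if (s[i] == 0) s[i] <- s[i + 1L]
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  count <- 0L
  for (i in seq_len(length(s) - 1L))
    if (s[i] != s[i + 1L]) count <- count + 1L
  count
}

# optimal tolerance matching count on instances where annotations are
# separated by more than twice the tolerance: each reference can only be
# served by detections in its private neighbourhood, so the optimum is the
# number of references with at least one detection in range
brute_match_count_spaced <- function(detected, reference, tol) {
  sum(vapply(reference,
             function(r) any(abs(detected - r) <= tol), logical(1)))
}

# short two-tone fixture used by several decomposition tests
two_tone <- function(duration = 20, fs = 250, f_fast = 10, f_slow = 1) {
  t <- seq(0, duration, by = 1 / fs)
  list(t = t, x = sin(2 * pi * f_fast * t) + sin(2 * pi * f_slow * t),
       fast = sin(2 * pi * f_fast * t), slow = sin(2 * pi * f_slow * t))
}

interior <- function(n, frac = 0.8) {
  k <- floor(n * (1 - frac) / 2)
  (k + 1L):(n - k)
}
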