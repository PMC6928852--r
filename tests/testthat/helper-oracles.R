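# Independent brute-force oracles used to cross-check the package's
# implementations. Kept deliberately naive and separate from the code paths
# they validate.

# Exhaustive neighbour-comparison extrema scan (no plateau handling; use on
# continuous random data where ties have probability zero).
brute_extrema <- function(x) {
  n <- length(x)
  mx <- mn <- integer()
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) mx <- c(mx, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) mn <- c(mn, i)
  }
  list(maxima = mx, minima = mn)
}

# Term-by-term entropy evaluations.
brute_shannon <- function(s) {
  tot <- 0
  for (v in s) if (v != 0) tot <- tot - v^2 * log(v^2)
  tot
}
brute_log_energy <- function(s) {
  tot <- 0
  for (v in s) if (v != 0) tot <- tot + log(v^2)
  tot
}
brute_norm <- function(s, p) {
  tot <- 0
  for (v in s) tot <- tot + abs(v)^p
  tot
}

# Central-moment cumulants evaluated longhand.
brute_cumulants <- function(s) {
  d <- s - mean(s)
  m2 <- sum(d^2) / length(s)
  m3 <- sum(d^3) / length(s)
  m4 <- sum(d^4) / length(s)
  c(m2, m3, m4 - 3 * m2^2)
}

# Exhaustive information-gain scan for the best single split of (x, y).
brute_best_split <- function(x, y) {
  ent <- function(lab) {
    p <- table(lab) / length(lab)
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  xs <- sort(unique(x))
  best <- list(gain = -Inf, threshold = NA)
  parent <- ent(y)
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    l <- y[x <= thr]; r <- y[x > thr]
    gain <- parent - (length(l) * ent(l) + length(r) * ent(r)) / length(y)
    if (gain > best$gain) best <- list(gain = gain, threshold = thr)
  }
  best
}

# Tallying oracle for confusion counts.
brute_confusion <- function(actual, predicted, lev) {
  m <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(actual))
    m[actual[i], predicted[i]] <- m[actual[i], predicted[i]] + 1L
  m
}

zero_crossings <- function(x) sum(diff(sign(x[x != 0])) != 0)

make_tone <- function(freq, n = 300, fs = 360, amp = 1) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs)
}
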