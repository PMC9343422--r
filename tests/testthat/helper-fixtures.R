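# Shared fixtures and independent oracles used across the suite.

# Small, fast three-cluster world: well-separated sources, high SNR, tilt.
small_cluster_spec <- function(seed, n_sensors = 6L, fs = 250, duration = 4,
                               clusters = list(1:2, 3:4, 5:6), ...) {
  sway_spec(n_sensors = n_sensors, fs = fs, duration = duration,
            clusters = clusters, seed = seed, ...)
}

# The full-scale world: 22 sensors, 1000 Hz, 20 s, three planted segments.
full_cluster_spec <- function(seed, ...) {
  sway_spec(clusters = list(1:8, 9:12, 13:22), seed = seed, ...)
}

# Brute-force complex mean phasor: explicit per-sample accumulation.
oracle_complex_sync <- function(phi_n, phi_m) {
  acc <- 0 + 0i
  for (t in seq_along(phi_n))
    acc <- acc + exp(1i * (phi_m[t] - phi_n[t]))
  acc / length(phi_n)
}

# Textbook Pearson r from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exhaustive maximal-window scan for coherent runs.
oracle_find_runs <- function(values, high) {
  np <- length(values)
  wins <- list()
  for (from in seq_len(np)) for (to in from:np) {
    if (all(values[from:to] >= high)) wins[[length(wins) + 1]] <- c(from, to + 1L)
  }
  # keep maximal windows only
  keep <- Filter(function(w) {
    !any(vapply(wins, function(o)
      (o[1] <= w[1] && o[2] >= w[2]) && !identical(o, w), logical(1)))
  }, wins)
  if (length(keep) == 0) return(data.frame(from = integer(0), to = integer(0)))
  m <- do.call(rbind, keep)
  data.frame(from = m[, 1], to = m[, 2])
}

# Closed-form squared magnitude of the bilinear-transform Butterworth
# low-pass (one pass); filtfilt applies it twice.
butter_gain <- function(f, fs, cutoff, order = 4) {
  1 / (1 + (tan(pi * f / fs) / tan(pi * cutoff / fs))^(2 * order))
}

expect_rows_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
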