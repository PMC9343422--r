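#' Instantaneous phase via the analytic signal
#'
#' Computes the Hilbert-transform analytic signal of a real series by the FFT
#' construction and returns its argument, the instantaneous phase, wrapped to
#' `(-pi, pi]`. The input must be de-meaned (a DC offset corrupts the
#' analytic-signal phase); [preprocess_recording()] guarantees this.
#'
#' @param x de-meaned numeric series.
#' @return numeric phase series, same length as `x`, values in `(-pi, pi]`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1e-3)[-1]
#' phi <- instantaneous_phase(sin(2 * pi * t))
#' # unwrapped slope is 2*pi rad/s
instantaneous_phase <- function(x) {
  if (stats::sd(x) == 0)
    stop("instantaneous_phase: constant series has undefined phase")
  n <- length(x)
  if (n < 100) stop("instantaneous_phase: need at least 100 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  Arg(analytic)
}

#' Complex mean phasor of a phase difference
#'
#' Averages `exp(i * (phi_m - phi_n))` over time. Its modulus is the phase
#' locking value (PLV) and its argument the mean phase angle between the two
#' series; `phi_m` is conventionally the more caudal sensor so a positive
#' angle means the caudal sensor leads.
#'
#' @param phi_n,phi_m phase series of equal length (radians).
#' @return a single complex number `v` with `Mod(v) <= 1`.
#' @export
complex_sync <- function(phi_n, phi_m) {
  if (length(phi_n) != length(phi_m))
    stop("complex_sync: phase series lengths differ")
  mean(exp(1i * (phi_m - phi_n)))
}

#' Signed synchronization index
#'
#' Collapses the complex mean phasor to the signed index
#' `V = |v| * cos(theta) / |cos(theta)|` with `theta = arg(v)`: the PLV
#' carrying the sign of the mean phase relation. `V` near `+1` means strong
#' in-phase locking, near `-1` strong anti-phase locking, near `0` weak
#' locking. The quotient is undefined at `theta = +/- pi/2`; when
#' `|cos(theta)| < 1e-12` the sign is defined as `+1` and the result carries
#' attribute `degenerate = TRUE`.
#'
#' @param v complex phasor with `Mod(v) <= 1` (from [complex_sync()]).
#' @return numeric `V` in `[-1, 1]`, with logical attribute `degenerate`.
#' @export
signed_sync_index <- function(v) {
  if (Mod(v) > 1 + 1e-9)
    stop("signed_sync_index: |v| > 1 is not a valid mean phasor")
  ct <- cos(Arg(v))
  degenerate <- abs(ct) < 1e-12
  s <- if (degenerate) 1 else sign(ct)
  structure(Mod(v) * s, degenerate = degenerate)
}

#' Pearson correlation of two acceleration series
#'
#' @param x_n,x_m numeric series of equal length with nonzero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
acceleration_correlation <- function(x_n, x_m) {
  if (length(x_n) != length(x_m))
    stop("acceleration_correlation: series lengths differ")
  if (stats::sd(x_n) == 0 || stats::sd(x_m) == 0)
    stop("acceleration_correlation: zero-variance series has undefined correlation")
  stats::cor(x_n, x_m)
}

#' Sensor-pair selections
#'
#' `adjacent_pairs(n)` gives the `n - 1` cranio-caudal neighbour pairs,
#' `all_sensor_pairs(n)` all `n (n - 1) / 2` combinations.
#'
#' @param n_sensors sensor count.
#' @return two-column integer matrix with columns `n`, `m` (`n < m`).
#' @export
adjacent_pairs <- function(n_sensors) {
  cbind(n = seq_len(n_sensors - 1L), m = 2:n_sensors)
}

#' @rdname adjacent_pairs
#' @export
all_sensor_pairs <- function(n_sensors) {
  t(utils::combn(n_sensors, 2L, FUN = as.integer)) |>
    (\(m) { colnames(m) <- c("n", "m"); m })()
}

#' Pairwise synchronization and similarity statistics
#'
#' For every requested sensor pair and both horizontal directions, computes
#' the phase locking value, mean phase angle, signed synchronization index
#' and Pearson acceleration correlation. Phases are extracted once per sensor
#' and a symmetric edge trim is applied to all phase series before averaging,
#' suppressing the Hilbert transform's boundary artifacts (the correlation
#' uses the same trimmed window so both statistics describe the same data).
#'
#' @param pre a `sway_preprocessed` recording.
#' @param pairs `"all"` (all combinations, default), `"adjacent"` (the
#'   neighbour pairs), or a two-column matrix of sensor indices `n < m`.
#' @param trim seconds discarded at each end of the phase series before
#'   averaging (default 0.5 s).
#' @return A long-format data frame with one row per pair and direction:
#'   `subject`, `condition`, `trial`, `direction`, `sensor_n`, `sensor_m`,
#'   `plv`, `theta`, `V`, `ac`, `degenerate`.
#' @export
#' @examples
#' rec <- generate_recording(sway_spec(n_sensors = 3, duration = 2, fs = 200,
#'                                     clusters = list(1:3), seed = 2))
#' all_pairs_sync(preprocess_recording(rec), pairs = "adjacent", trim = 0.2)
all_pairs_sync <- function(pre, pairs = "all", trim = 0.5) {
  stopifnot(inherits(pre, "sway_preprocessed"))
  ns <- ncol(pre$ml)
  if (is.character(pairs)) {
    pairs <- switch(match.arg(pairs, c("all", "adjacent")),
                    all = all_sensor_pairs(ns),
                    adjacent = adjacent_pairs(ns))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2 || any(pairs[, 1] >= pairs[, 2]) ||
      any(pairs < 1) || any(pairs > ns))
    stop("all_pairs_sync: pairs must be two columns of sensor indices n < m")
  n_t <- nrow(pre$ml)
  k <- round(trim * pre$fs)
  if (2 * k >= n_t - 100)
    stop("all_pairs_sync: trim leaves too few samples")
  keep <- (k + 1):(n_t - k)
  out <- vector("list", 2L)
  for (di in 1:2) {
    dirname <- c("ML", "AP")[di]
    mat <- if (di == 1) pre$ml else pre$ap
    phases <- apply(mat, 2, instantaneous_phase)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      n <- pairs[i, 1]; m <- pairs[i, 2]
      v <- complex_sync(phases[keep, n], phases[keep, m])
      V <- signed_sync_index(v)
      data.frame(subject = pre$subject_id, condition = pre$condition,
                 trial = pre$trial_index, direction = dirname,
                 sensor_n = n, sensor_m = m,
                 plv = Mod(v), theta = Arg(v), V = as.numeric(V),
                 ac = acceleration_correlation(mat[keep, n], mat[keep, m]),
                 degenerate = attr(V, "degenerate"))
    })
    out[[di]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
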