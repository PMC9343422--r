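# Standard gravity used throughout (m/s^2).
GRAVITY <- 9.81

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise restricted to a frequency band by zeroing Fourier
#' coefficients outside `[low, high]` Hz, then rescaled to unit standard
#' deviation. This is the elementary sway source of the simulator: Gaussian,
#' stationary, with all spectral mass inside the band.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param band numeric `c(low, high)` in Hz, `0 < low < high < fs/2`.
#' @return numeric vector of length `n` with `sd(x) == 1`.
#' @export
band_limited_noise <- function(n, fs, band = c(0.1, 3)) {
  stopifnot(n > 2, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # fold to two-sided frequency magnitude
  X[f < band[1] | f > band[2]] <- 0
  s <- Re(stats::fft(X, inverse = TRUE)) / n
  s / stats::sd(s)
}

circular_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[seq_len(n - k)])
}

# pitch about the ML (x) axis; columns are world axes (ML, AP, vertical)
rotation_pitch <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(1, 0, 0,
           0, c_, -s_,
           0, s_, c_), 3, 3, byrow = TRUE)
}

#' Generate a synthetic multi-segment sway recording
#'
#' Simulates one trial of quiet standing measured by a chain of tri-axial
#' accelerometers. Every sensor of a cluster shares that cluster's
#' band-limited Gaussian sway source (scaled by amplitude and per-sensor
#' polarity, optionally delayed), mixed with `cross_coupling` times a global
#' source shared by all clusters. Independent white noise is added per sensor
#' and axis, gravity is added on the vertical axis, and each sensor's static
#' tilt is applied last, so the output is what a tilted sensor would actually
#' read. ML and AP directions receive independent sources.
#'
#' @param spec a [sway_spec()].
#' @return An object of class `sway_recording`: a list with the metadata
#'   fields `subject_id`, `condition`, `trial_index`, `fs` and `data`, a
#'   `T x n_sensors x 3` array of accelerations in m/s^2 (axes `x` = nominal
#'   ML, `y` = nominal AP, `z` = nominal vertical, in the sensor frame).
#' @param subject_id,condition,trial_index metadata stamped on the recording.
#' @export
#' @examples
#' rec <- generate_recording(sway_spec(n_sensors = 4, duration = 2, fs = 200,
#'                                     clusters = list(1:2, 3:4), seed = 7))
#' dim(rec$data)
generate_recording <- function(spec, subject_id = "sim", condition = "EO",
                               trial_index = 1L) {
  validate_sway_spec(spec)
  n <- round(spec$fs * spec$duration)
  ns <- spec$n_sensors
  with_seed(spec$seed, {
    # directions are simulated independently; the global source is shared
    global <- list(ML = band_limited_noise(n, spec$fs, spec$band[[1]]),
                   AP = band_limited_noise(n, spec$fs, spec$band[[1]]))
    dat <- array(0, dim = c(n, ns, 3),
                 dimnames = list(NULL, sprintf("s%02d", seq_len(ns)),
                                 c("x", "y", "z")))
    for (ci in seq_along(spec$clusters)) {
      lagk <- round(spec$lag[ci] * spec$fs)
      for (d in c(1, 2)) {  # 1 = ML/x, 2 = AP/y
        src <- band_limited_noise(n, spec$fs, spec$band[[ci]])
        src <- circular_shift(src, lagk)
        dname <- c("ML", "AP")[d]
        mixed <- spec$amplitude[ci] * src +
          spec$cross_coupling * global[[dname]]
        for (s in spec$clusters[[ci]])
          dat[, s, d] <- spec$polarity[s] * mixed
      }
    }
    for (s in seq_len(ns)) {
      if (spec$noise_sd[s] > 0)
        dat[, s, ] <- dat[, s, ] +
          matrix(stats::rnorm(3L * n, sd = spec$noise_sd[s]), n, 3)
      dat[, s, 3] <- dat[, s, 3] + GRAVITY
      if (spec$tilt[s] != 0) {
        # sensor frame reading: inverse tilt applied to the world vector
        R <- t(rotation_pitch(spec$tilt[s]))
        dat[, s, ] <- dat[, s, ] %*% t(R)
      }
    }
    structure(list(subject_id = subject_id, condition = condition,
                   trial_index = as.integer(trial_index), fs = spec$fs,
                   data = dat),
              class = "sway_recording")
  })
}

#' @export
print.sway_recording <- function(x, ...) {
  cat(sprintf(
    "<sway_recording> subject %s, %s, trial %d: %d sensors x %d samples @ %g Hz\n",
    x$subject_id, x$condition, x$trial_index,
    dim(x$data)[2], dim(x$data)[1], x$fs))
  invisible(x)
}
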