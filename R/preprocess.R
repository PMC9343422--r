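#' Butterworth low-pass design
#'
#' Designs a digital Butterworth low-pass filter by bilinear transform of the
#' analog prototype with frequency pre-warping. The squared magnitude of the
#' resulting digital filter has the closed form
#' `|H(f)|^2 = 1 / (1 + (tan(pi f / fs) / tan(pi fc / fs))^(2 order))`,
#' which the test-suite uses as an independent oracle.
#'
#' @param order filter order (default 4).
#' @param cutoff -3 dB cutoff frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @keywords internal
butter_lowpass <- function(order = 4L, cutoff, fs) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("butter_lowpass: cutoff must lie in (0, fs/2)")
  wc <- 2 * fs * tan(pi * cutoff / fs)           # pre-warped analog cutoff
  k <- seq_len(order)
  p <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  z <- (2 * fs + p) / (2 * fs - p)               # bilinear transform of poles
  co <- 1 + 0i
  for (zi in z) co <- c(co, 0) - c(0, co * zi)   # polynomial from roots
  a <- Re(co)
  b <- choose(order, 0:order)                    # order-fold zero at z = -1
  list(b = b * sum(a) / sum(b), a = a)           # unit DC gain
}

# Single forward IIR pass. The initial filter state is the steady state for a
# constant input equal to x[1], so constant series pass through exactly.
iir_forward <- function(b, a, x) {
  ord <- length(a) - 1L
  xp <- c(rep(x[1], ord), x)
  u <- stats::filter(xp, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[-seq_len(ord)]
  y0 <- x[1] * sum(b) / sum(a)
  as.numeric(stats::filter(u, -a[-1], method = "recursive",
                           init = rep(y0, ord)))
}

#' Zero-phase low-pass filtering
#'
#' Applies a Butterworth low-pass filter forward and backward (filtfilt), so
#' the net filter has zero phase shift at all frequencies and squared
#' magnitude response; this protects the downstream instantaneous-phase
#' analysis from filter-induced phase distortion. Edges are handled by odd
#' reflection padding plus steady-state initial conditions.
#'
#' @param x numeric vector, or a matrix filtered column-wise.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (default 20, removing high-frequency
#'   noise while keeping the sway band intact).
#' @param order Butterworth order of each pass (default 4).
#' @return filtered series, same length/shape as `x`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' max(abs(lowpass_filter(sin(2 * pi * 5 * t), fs = 1000)))  # passband: ~1
lowpass_filter <- function(x, fs, cutoff = 20, order = 4L) {
  if (is.matrix(x)) return(apply(x, 2, lowpass_filter, fs = fs,
                                 cutoff = cutoff, order = order))
  co <- butter_lowpass(order, cutoff, fs)
  n <- length(x)
  padlen <- min(n - 1L, 15L * (order + 1L))
  if (n <= order + 1L)
    stop("lowpass_filter: series too short for the filter order")
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- iir_forward(co$b, co$a, c(pre, x, post))
  y <- rev(iir_forward(co$b, co$a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Estimate initial sensor orientation from a static window
#'
#' During the first moments of quiet standing the dynamic acceleration is
#' small, so the window-mean of each sensor's reading points along gravity in
#' the sensor frame. For each sensor this returns the minimal-angle rotation
#' that maps the measured gravity direction onto the world vertical axis;
#' rotation about the vertical (heading) is left unresolved by construction,
#' the nominal mounting defining ML and AP.
#'
#' @param rec a `sway_recording`.
#' @param static_window seconds of data from the start of the trial used for
#'   the estimate (default 1 s).
#' @return An object of class `sway_orientation`: a list of 3x3 rotation
#'   matrices, one per sensor, mapping sensor-frame vectors to the world
#'   frame.
#' @export
estimate_initial_orientation <- function(rec, static_window = 1) {
  stopifnot(inherits(rec, "sway_recording"))
  n <- dim(rec$data)[1]
  k <- min(n, max(2L, round(static_window * rec$fs)))
  rots <- lapply(seq_len(dim(rec$data)[2]), function(s) {
    g <- colMeans(rec$data[seq_len(k), s, , drop = FALSE][, 1, ])
    nrm <- sqrt(sum(g^2))
    if (nrm < 0.5 * GRAVITY)
      stop(sprintf(
        "estimate_initial_orientation: sensor %d window mean |a| = %.2f m/s^2 is below 0.5 g; window is not quasi-static",
        s, nrm))
    rotation_to_vertical(g / nrm)
  })
  structure(rots, class = "sway_orientation")
}

# Minimal rotation taking unit vector u onto (0, 0, 1) (Rodrigues formula).
rotation_to_vertical <- function(u) {
  e <- c(0, 0, 1)
  v <- c(u[2] * e[3] - u[3] * e[2],
         u[3] * e[1] - u[1] * e[3],
         u[1] * e[2] - u[2] * e[1])
  c_ <- sum(u * e)
  s2 <- sum(v^2)
  if (s2 < 1e-20) {
    if (c_ > 0) return(diag(3))
    # u anti-parallel to vertical: rotate pi about the ML axis
    return(rotation_pitch(pi))
  }
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

#' Rotate a recording into the world frame
#'
#' Applies a per-sensor orientation estimate so each sensor's series is
#' expressed in world axes: `x` = ML, `y` = AP, `z` = vertical (gravity
#' pointing along +z). Rotation preserves vector norms sample by sample.
#'
#' @param rec a `sway_recording`.
#' @param orient a `sway_orientation` from [estimate_initial_orientation()].
#' @return a `sway_recording` in the world frame.
#' @export
correct_orientation <- function(rec, orient) {
  stopifnot(inherits(rec, "sway_recording"), inherits(orient, "sway_orientation"))
  ns <- dim(rec$data)[2]
  if (length(orient) != ns)
    stop(sprintf("correct_orientation: %d sensors but %d orientation estimates",
                 ns, length(orient)))
  out <- rec
  for (s in seq_len(ns))
    out$data[, s, ] <- rec$data[, s, ] %*% t(orient[[s]])
  out
}

#' Preprocess a raw recording for synchronization analysis
#'
#' Runs the standard chain: estimate initial orientation from the static
#' window, rotate into the world frame, extract the horizontal ML and AP
#' components, low-pass filter them with a zero-phase Butterworth filter and
#' remove each series' mean. The vertical component is retained, unfiltered,
#' for diagnostics only.
#'
#' @param rec a `sway_recording`.
#' @param cutoff low-pass cutoff, Hz (default 20).
#' @param static_window orientation-estimation window, seconds (default 1).
#' @param order Butterworth order (default 4).
#' @return An object of class `sway_preprocessed`: metadata plus `T x n`
#'   matrices `ml` and `ap` of filtered, de-meaned horizontal accelerations,
#'   and `vertical` (world-frame, unprocessed).
#' @export
preprocess_recording <- function(rec, cutoff = 20, static_window = 1,
                                 order = 4L) {
  orient <- estimate_initial_orientation(rec, static_window)
  world <- correct_orientation(rec, orient)
  ml <- lowpass_filter(world$data[, , 1], fs = rec$fs, cutoff = cutoff,
                       order = order)
  ap <- lowpass_filter(world$data[, , 2], fs = rec$fs, cutoff = cutoff,
                       order = order)
  ml <- sweep(ml, 2, colMeans(ml))
  ap <- sweep(ap, 2, colMeans(ap))
  structure(list(subject_id = rec$subject_id, condition = rec$condition,
                 trial_index = rec$trial_index, fs = rec$fs,
                 ml = ml, ap = ap, vertical = world$data[, , 3]),
            class = "sway_preprocessed")
}

#' @export
print.sway_preprocessed <- function(x, ...) {
  cat(sprintf(
    "<sway_preprocessed> subject %s, %s, trial %d: %d sensors x %d samples @ %g Hz (ML, AP)\n",
    x$subject_id, x$condition, x$trial_index, ncol(x$ml), nrow(x$ml), x$fs))
  invisible(x)
}
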