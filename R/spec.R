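#' Describe a synthetic multi-segment sway recording
#'
#' A `sway_spec` is the generative description of one synthetic accelerometer
#' recording of quiet standing: a chain of sensors partitioned into contiguous
#' rigid clusters, each cluster driven by its own band-limited sway source,
#' with optional global coupling, per-sensor noise, gravity and static tilt.
#' It is the ground truth against which the segmentation pipeline can be
#' validated.
#'
#' @param n_sensors number of sensors along the head-trunk axis (default 22).
#' @param fs sampling rate in Hz (default 1000).
#' @param duration recording length in seconds (default 20).
#' @param clusters ordered partition of `1:n_sensors` into contiguous blocks,
#'   as a list of integer vectors. Blocks must be disjoint, contiguous and
#'   cover all sensors in order. Default: one cluster spanning all sensors.
#' @param band two-element numeric `c(low, high)` in Hz bounding the sway
#'   source spectrum, or a list with one band per cluster. Must satisfy
#'   `0 < low < high < fs/2`. Default `c(0.1, 3)`, the typical postural-sway
#'   band, well below the 20 Hz analysis cutoff.
#' @param amplitude source amplitude in m/s^2 (scalar or per cluster).
#'   Default 0.05 m/s^2, a realistic trunk sway acceleration RMS.
#' @param polarity per-sensor sign, `+1` for in-phase, `-1` for anti-phase
#'   coupling to the cluster source. Default all `+1`.
#' @param lag per-cluster delay of the cluster source in seconds, applied as a
#'   circular shift. Default 0.
#' @param cross_coupling coefficient in `[0, 1]` mixing a shared global source
#'   into every cluster. Default 0 (clusters fully independent).
#' @param noise_sd per-sensor white measurement noise SD in m/s^2 (scalar or
#'   per sensor). Default 0.005 (power SNR 100 against the default amplitude).
#' @param tilt per-sensor static pitch (rotation about the ML axis) in
#'   radians, applied to the true acceleration-plus-gravity vector before
#'   output. Default 0.
#' @param seed integer seed making the recording fully reproducible.
#'
#' @return An object of class `sway_spec`.
#' @seealso [generate_recording()], [ground_truth_segmentation()]
#' @export
#' @examples
#' spec <- sway_spec(clusters = list(1:8, 9:12, 13:22), seed = 1)
#' ground_truth_segmentation(spec)
sway_spec <- function(n_sensors = 22L, fs = 1000, duration = 20,
                      clusters = list(seq_len(n_sensors)),
                      band = c(0.1, 3),
                      amplitude = 0.05,
                      polarity = rep(1, n_sensors),
                      lag = 0,
                      cross_coupling = 0,
                      noise_sd = 0.005,
                      tilt = rep(0, n_sensors),
                      seed = 1L) {
  spec <- structure(list(
    n_sensors = as.integer(n_sensors), fs = fs, duration = duration,
    clusters = lapply(clusters, as.integer),
    band = if (is.list(band)) band else rep(list(band), length(clusters)),
    amplitude = rep_len(amplitude, length(clusters)),
    polarity = rep_len(polarity, n_sensors),
    lag = rep_len(lag, length(clusters)),
    cross_coupling = cross_coupling,
    noise_sd = rep_len(noise_sd, n_sensors),
    tilt = rep_len(tilt, n_sensors),
    seed = as.integer(seed)
  ), class = "sway_spec")
  validate_sway_spec(spec)
  spec
}

validate_sway_spec <- function(spec) {
  with(spec, {
    if (n_sensors < 2) stop("sway_spec: need at least 2 sensors")
    if (fs <= 0 || duration <= 0) stop("sway_spec: fs and duration must be positive")
    flat <- unlist(clusters)
    if (!identical(flat, seq_len(n_sensors)))
      stop("sway_spec: clusters must be disjoint contiguous blocks covering 1..n_sensors in order")
    for (b in band) {
      if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1] || b[2] >= fs / 2)
        stop("sway_spec: band must satisfy 0 < low < high < fs/2")
    }
    if (any(noise_sd < 0)) stop("sway_spec: noise_sd must be >= 0")
    if (!all(polarity %in% c(-1, 1))) stop("sway_spec: polarity must be +1 or -1")
    if (cross_coupling < 0 || cross_coupling > 1)
      stop("sway_spec: cross_coupling must be in [0, 1]")
  })
  invisible(spec)
}

#' @export
print.sway_spec <- function(x, ...) {
  cat(sprintf("<sway_spec> %d sensors, %g Hz, %g s, %d cluster(s), seed %d\n",
              x$n_sensors, x$fs, x$duration, length(x$clusters), x$seed))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: sensors %d-%d, band %g-%g Hz, amplitude %g\n",
                i, min(cl), max(cl), x$band[[i]][1], x$band[[i]][2], x$amplitude[i]))
  }
  invisible(x)
}

#' Ground-truth segmentation implied by a simulation spec
#'
#' Returns the adjacent sensor pairs that straddle a cluster boundary (the
#' planted "link sites") and the cluster runs themselves, i.e. what a perfect
#' segmentation analysis should recover from a recording generated from
#' `spec`.
#'
#' @param spec a [sway_spec()].
#' @return A list of class `sway_ground_truth` with elements
#'   `link_pairs` (two-column integer matrix, one row per boundary pair
#'   `(n, n+1)`) and `cluster_runs` (data frame with columns `from`, `to`).
#' @export
ground_truth_segmentation <- function(spec) {
  validate_sway_spec(spec)
  runs <- data.frame(
    from = vapply(spec$clusters, min, integer(1)),
    to = vapply(spec$clusters, max, integer(1))
  )
  bounds <- runs$to[-nrow(runs)]
  link_pairs <- cbind(n = bounds, m = bounds + 1L)
  structure(list(link_pairs = link_pairs, cluster_runs = runs),
            class = "sway_ground_truth")
}

#' Read or write a simulation spec as JSON
#'
#' Plain-text (JSON) serialization of a [sway_spec()], used by the command
#' line interface.
#'
#' @param spec a `sway_spec`.
#' @param path file path.
#' @return `write_sway_spec` returns `path` invisibly; `read_sway_spec`
#'   returns a `sway_spec`.
#' @export
write_sway_spec <- function(spec, path) {
  validate_sway_spec(spec)
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sway_spec
#' @export
read_sway_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- function(m) {
    if (is.matrix(m)) lapply(seq_len(nrow(m)), function(i) m[i, ])
    else if (is.list(m)) m
    else list(m)
  }
  sway_spec(n_sensors = x$n_sensors, fs = x$fs, duration = x$duration,
            clusters = rows(x$clusters),
            band = rows(x$band),
            amplitude = x$amplitude, polarity = x$polarity, lag = x$lag,
            cross_coupling = x$cross_coupling, noise_sd = x$noise_sd,
            tilt = x$tilt, seed = x$seed)
}
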