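#' Average pairwise statistics over a subject's trials
#'
#' Collapses the per-trial output of [all_pairs_sync()] (possibly row-bound
#' over several trials and subjects) to one row per subject, condition,
#' direction and sensor pair, taking the arithmetic mean of the signed index
#' `V` and the correlation `ac` across trials. With `rule = "first"` only the
#' first trial is kept instead.
#'
#' @param sync_df long-format data frame from [all_pairs_sync()].
#' @param rule `"mean"` (default) or `"first"`.
#' @return data frame with columns `subject`, `condition`, `direction`,
#'   `sensor_n`, `sensor_m`, `V`, `ac`, `n_trials`.
#' @export
average_over_trials <- function(sync_df, rule = c("mean", "first")) {
  rule <- match.arg(rule)
  if (nrow(sync_df) == 0) stop("average_over_trials: no trials supplied")
  dt <- data.table::as.data.table(sync_df)
  if (rule == "first") {
    dt <- dt[, .SD[trial == min(trial)],
             by = c("subject", "condition", "direction")]
  }
  out <- dt[, list(V = mean(V), ac = mean(ac), n_trials = .N),
            by = c("subject", "condition", "direction",
                   "sensor_n", "sensor_m")]
  as.data.frame(out)
}

#' Similarity / synchronization category bands
#'
#' Bands a mean similarity or synchronization value into the four standard
#' categories: `VS` ("very strong", `>= 0.8`), `S` ("strong", `[0.6, 0.8)`),
#' `M` ("moderate", `[0.4, 0.6)`) and `W` ("weak", `< 0.4`; all negative
#' values are weak). Band boundaries are closed at the lower edge, so 0.4,
#' 0.6 and 0.8 land in `M`, `S` and `VS` respectively.
#'
#' @param value numeric vector of means in `[-1, 1]`.
#' @return factor with levels `VS`, `S`, `M`, `W`.
#' @export
#' @examples
#' categorize(c(0.84, 0.80, 0.60, 0.40, 0.39, -0.2))
categorize <- function(value) {
  if (any(value < -1 - 1e-9 | value > 1 + 1e-9))
    stop("categorize: values must lie in [-1, 1]")
  factor(ifelse(value >= 0.8, "VS",
         ifelse(value >= 0.6, "S",
         ifelse(value >= 0.4, "M", "W"))),
         levels = c("VS", "S", "M", "W"))
}

#' Across-subject mean and SD with category labels
#'
#' Computes the across-subject mean and sample standard deviation
#' (denominator `n - 1`) of a chosen per-subject statistic for every
#' condition, direction and sensor pair, and attaches the similarity
#' category of the mean. Applied to `ac` this yields the group average
#' acceleration correlation (AAC); applied to `V` the group average
#' phase-locking index (APLV; the signed index is averaged by default, see
#' `metric = "plv"` for strict magnitude averaging).
#'
#' @param subject_df output of [average_over_trials()] (for `metric = "plv"`,
#'   a column `plv` must be present, i.e. carry it through beforehand).
#' @param metric which per-subject column to aggregate: `"ac"`, `"V"`, or
#'   `"plv"`.
#' @return data frame with `condition`, `direction`, `sensor_n`, `sensor_m`,
#'   `mean`, `sd`, `n_subjects`, `category`, `region` (for adjacent pairs).
#' @export
group_mean_sd <- function(subject_df, metric = c("ac", "V", "plv")) {
  metric <- match.arg(metric)
  if (!metric %in% names(subject_df))
    stop(sprintf("group_mean_sd: column '%s' not found", metric))
  dt <- data.table::as.data.table(subject_df)
  data.table::setnames(dt, metric, "metric_value")
  out <- dt[, list(mean = mean(metric_value), sd = stats::sd(metric_value),
                   n_subjects = .N),
            by = c("condition", "direction", "sensor_n", "sensor_m")]
  if (any(out$n_subjects < 2))
    stop("group_mean_sd: need at least 2 subjects per cell")
  out <- as.data.frame(out)
  out$category <- categorize(out$mean)
  adj <- out$sensor_m == out$sensor_n + 1L
  out$region <- NA_character_
  out$region[adj] <- region_label(out$sensor_n[adj], out$sensor_m[adj])
  out
}

#' Anatomical region of an adjacent sensor pair
#'
#' Maps an adjacent pair `(n, n + 1)` of the 22-sensor cranio-caudal montage
#' to the anatomical region it spans, from the head down to the pelvis.
#'
#' @param n,m sensor indices with `m == n + 1`, `1 <= n < m <= 22`
#'   (vectorized).
#' @return character vector of region names.
#' @export
#' @examples
#' region_label(1, 2)
#' region_label(10, 11)
region_label <- function(n, m) {
  if (any(m != n + 1) || any(n < 1) || any(m > 22))
    stop("region_label: defined for adjacent pairs (n, n+1) with 1 <= n < m <= 22")
  regions <- c("head and upper neck",              # pair 1-2
               rep("upper neck", 2),               # 2-3, 3-4
               rep("lower neck", 2),               # 4-5, 5-6
               rep("upper thorax", 3),             # 6-7 .. 8-9
               rep("middle thorax", 3),            # 9-10 .. 11-12
               rep("lower thorax", 3),             # 12-13 .. 14-15
               rep("upper lumbar", 3),             # 15-16 .. 17-18
               rep("lower lumbar", 3),             # 18-19 .. 20-21
               "lower lumbar and pelvis")          # 21-22
  regions[n]
}

#' Coherent clusters and link sites along the sensor chain
#'
#' Scans the ordered adjacent-pair values (pair 1-2 first, most caudal pair
#' last) for maximal runs of sensors whose every internal adjacent pair
#' meets the `high` threshold (coherent, stiff segments) and for pairs below
#' the `low` threshold (link sites, i.e. compliant joints between segments).
#' Pairs with values in `[low, high)` belong to neither set. A single
#' qualifying pair is reported as a two-sensor run.
#'
#' @param adjacent_values numeric vector of `n_sensors - 1` adjacent-pair
#'   means in cranio-caudal order.
#' @param high coherence threshold (default 0.6; value `>= high` qualifies).
#' @param low link threshold (default 0.4; value `< low` is a link site).
#' @param n_sensors total sensor count (default `length(adjacent_values)+1`).
#' @return An object of class `sway_segmentation`: list with `values`,
#'   `coherent_runs` (data frame `from`, `to` in sensor indices),
#'   `link_sites` (data frame `n`, `m`), `high`, `low`, and `region` labels
#'   when `n_sensors == 22`.
#' @export
#' @examples
#' v <- c(0.9, 0.9, 0.2, 0.7, 0.7)
#' find_clusters(v)  # run 1-3, run 4-6, link site (3, 4)
find_clusters <- function(adjacent_values, high = 0.6, low = 0.4,
                          n_sensors = length(adjacent_values) + 1L) {
  if (length(adjacent_values) != n_sensors - 1L)
    stop(sprintf("find_clusters: expected %d adjacent values, got %d",
                 n_sensors - 1L, length(adjacent_values)))
  if (low > high) stop("find_clusters: low threshold exceeds high threshold")
  qualifies <- adjacent_values >= high
  runs <- rle(qualifies)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  coh <- data.frame(from = integer(0), to = integer(0))
  for (i in seq_along(runs$values)) {
    if (runs$values[i])
      coh <- rbind(coh, data.frame(from = starts[i], to = ends[i] + 1L))
  }
  links_idx <- which(adjacent_values < low)
  link_sites <- data.frame(n = links_idx, m = links_idx + 1L)
  res <- list(values = adjacent_values, coherent_runs = coh,
              link_sites = link_sites, high = high, low = low)
  if (n_sensors == 22L) {
    res$region <- region_label(seq_len(21L), 2:22)
  }
  structure(res, class = "sway_segmentation")
}

#' @export
print.sway_segmentation <- function(x, ...) {
  cat(sprintf("<sway_segmentation> high >= %g, low < %g\n", x$high, x$low))
  if (nrow(x$coherent_runs) == 0) cat("  coherent runs: none\n")
  else cat("  coherent runs:",
           paste(sprintf("%d-%d", x$coherent_runs$from, x$coherent_runs$to),
                 collapse = ", "), "\n")
  if (nrow(x$link_sites) == 0) cat("  link sites: none\n")
  else cat("  link sites:",
           paste(sprintf("(%d,%d)", x$link_sites$n, x$link_sites$m),
                 collapse = ", "), "\n")
  invisible(x)
}

#' Bundled group-level reference statistics
#'
#' Loads the published group-level adjacent-pair statistics that ship with
#' the package (across-subject mean, SD and category of the acceleration
#' correlation, AAC, and of the phase-locking index, APLV, for a ten-subject
#' 22-sensor quiet-standing study under eyes-open and eyes-closed
#' conditions). Useful as demonstration input for [find_clusters()] and
#' [render_heatmaps()].
#'
#' @return data frame with columns `metric` (`AAC`/`APLV`), `direction`
#'   (`ML`/`AP`), `condition` (`EO`/`EC`), `sensor_n`, `sensor_m`, `mean`,
#'   `sd`, `category`.
#' @export
reference_group_stats <- function() {
  path <- system.file("extdata", "reference_group_stats.csv",
                      package = "swaysync", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Render mean and SD heat maps of pairwise statistics
#'
#' Writes one PNG per condition x direction combination, showing the pairwise
#' matrix of the group mean and (if present) its standard deviation, axes
#' labelled by sensor number. Cells never computed (e.g. non-adjacent pairs
#' of an adjacent-only analysis) are left blank and a warning is logged.
#'
#' @param group_df output of [group_mean_sd()] (or any data frame with
#'   `condition`, `direction`, `sensor_n`, `sensor_m`, `mean`, and optionally
#'   `sd`).
#' @param out_dir output directory, created if needed.
#' @param n_sensors matrix size (default 22).
#' @param width,height device size in pixels.
#' @return character vector of file paths written, invisibly.
#' @export
render_heatmaps <- function(group_df, out_dir, n_sensors = 22L,
                            width = 700L, height = 600L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  combos <- unique(group_df[, c("condition", "direction")])
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  full <- n_sensors * (n_sensors - 1) / 2
  for (i in seq_len(nrow(combos))) {
    sub <- group_df[group_df$condition == combos$condition[i] &
                      group_df$direction == combos$direction[i], ]
    if (nrow(sub) < full)
      warning(sprintf("render_heatmaps: %s/%s has %d of %d pairs; missing cells masked",
                      combos$condition[i], combos$direction[i], nrow(sub), full))
    for (what in intersect(c("mean", "sd"), names(sub))) {
      m <- matrix(NA_real_, n_sensors, n_sensors)
      idx <- cbind(sub$sensor_n, sub$sensor_m)
      m[idx] <- sub[[what]]
      m[idx[, c(2, 1), drop = FALSE]] <- sub[[what]]
      fn <- file.path(out_dir, sprintf("%s_%s_%s.png", what,
                                       combos$condition[i],
                                       combos$direction[i]))
      grDevices::png(fn, width = width, height = height)
      graphics::par(mar = c(4, 4, 3, 2))
      graphics::image(seq_len(n_sensors), seq_len(n_sensors),
                      m[, rev(seq_len(n_sensors))],
                      zlim = range(group_df[[what]], 0, 1, na.rm = TRUE),
                      col = pal, xlab = "sensor", ylab = "sensor",
                      main = sprintf("%s (%s, %s)", toupper(what),
                                     combos$condition[i],
                                     combos$direction[i]),
                      axes = FALSE)
      graphics::axis(1, at = seq_len(n_sensors), cex.axis = 0.6)
      graphics::axis(2, at = seq_len(n_sensors),
                     labels = rev(seq_len(n_sensors)), cex.axis = 0.6)
      grDevices::dev.off()
      paths <- c(paths, fn)
    }
  }
  invisible(paths)
}
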