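#' Write a recording to the plain-text exchange format
#'
#' The on-disk format is delimiter-separated text with a comment header:
#' ```
#' # subject=<id>
#' # condition=<EO|EC>
#' # trial=<int>
#' # fs=<Hz>
#' time_s  s01_x  s01_y  s01_z  ...  s22_z
#' ```
#' followed by one row per sample, accelerations in m/s^2.
#'
#' @param rec a `sway_recording`.
#' @param path output file path.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = "\t") {
  stopifnot(inherits(rec, "sway_recording"))
  d <- dim(rec$data)
  ns <- d[2]
  cols <- as.vector(t(outer(sprintf("s%02d", seq_len(ns)), c("x", "y", "z"),
                            paste, sep = "_")))
  flat <- matrix(aperm(rec$data, c(1, 3, 2)), nrow = d[1])  # sensor-major cols
  dt <- data.table::as.data.table(flat)
  data.table::setnames(dt, cols)
  dt <- cbind(data.table::data.table(time_s = (seq_len(d[1]) - 1) / rec$fs), dt)
  hdr <- c(sprintf("# subject=%s", rec$subject_id),
           sprintf("# condition=%s", rec$condition),
           sprintf("# trial=%d", rec$trial_index),
           sprintf("# fs=%g", rec$fs))
  writeLines(hdr, path)
  data.table::fwrite(dt, path, sep = sep, append = TRUE, col.names = TRUE)
  invisible(path)
}

parse_header <- function(lines, path) {
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([a-zA-Z_]+)\\s*=\\s*(.+)\\s*$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  for (need in c("subject", "condition", "trial", "fs"))
    if (is.null(kv[[need]]))
      stop(sprintf("recording %s: missing '# %s=' header line", path, need))
  if (!kv$condition %in% c("EO", "EC"))
    stop(sprintf("recording %s: condition must be EO or EC, got '%s'",
                 path, kv$condition))
  kv
}

#' Read a recording from the plain-text exchange format
#'
#' Parses the format written by [write_recording()]: four `# key=value`
#' header lines, a `time_s` column and `sNN_{x,y,z}` columns ordered
#' cranial-to-caudal. Malformed files (missing columns, non-numeric cells,
#' ragged rows, empty body) raise an error naming the problem.
#'
#' @param path file path.
#' @return A `sway_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  head_lines <- readLines(path, n = 20L)
  kv <- parse_header(head_lines[startsWith(head_lines, "#")], path)
  dt <- tryCatch(
    data.table::fread(path, skip = length(which(startsWith(head_lines, "#"))),
                      header = TRUE, sep = "auto", fill = FALSE),
    error = function(e) stop(sprintf("recording %s: malformed table (%s)",
                                     path, conditionMessage(e))))
  if (nrow(dt) == 0)
    stop(sprintf("recording %s: header present but no data rows", path))
  if (!"time_s" %in% names(dt))
    stop(sprintf("recording %s: missing column time_s", path))
  sensor_cols <- grep("^s[0-9]{2}_[xyz]$", names(dt), value = TRUE)
  ids <- sort(unique(as.integer(substr(sensor_cols, 2, 3))))
  if (length(ids) == 0) stop(sprintf("recording %s: no sensor columns", path))
  expect <- as.vector(t(outer(sprintf("s%02d", ids), c("x", "y", "z"),
                              paste, sep = "_")))
  missing <- setdiff(expect, sensor_cols)
  if (length(missing) > 0)
    stop(sprintf("recording %s: missing columns %s", path,
                 paste(missing, collapse = ", ")))
  bad <- expect[!vapply(dt[, expect, with = FALSE], is.numeric, logical(1))]
  if (length(bad) > 0)
    stop(sprintf("recording %s: non-numeric cells in columns %s", path,
                 paste(bad, collapse = ", ")))
  n <- nrow(dt)
  dat <- array(NA_real_, dim = c(n, length(ids), 3),
               dimnames = list(NULL, sprintf("s%02d", ids), c("x", "y", "z")))
  for (i in seq_along(ids)) for (ai in 1:3)
    dat[, i, ai] <- dt[[sprintf("s%02d_%s", ids[i], c("x", "y", "z")[ai])]]
  structure(list(subject_id = kv$subject, condition = kv$condition,
                 trial_index = as.integer(kv$trial), fs = as.numeric(kv$fs),
                 data = dat),
            class = "sway_recording")
}
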