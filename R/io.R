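#' Construct a track table
#'
#' A track table is a long-format data.frame with one row per (frame, bee):
#' `frame` (0-based), `time_s` (= frame / frame rate), `bee_id` (the label
#' "focal" is reserved for the recorded bee), `x_cm`, `y_cm`, `theta_deg`
#' (long-body-axis direction in arena coordinates, degrees in [0, 360)).
#' Bees may be absent from some frames (tracker dropouts); downstream
#' nearest-bee searches simply skip them in those frames.
#'
#' @param frame,time_s,bee_id,x_cm,y_cm,theta_deg column vectors.
#' @param frame_rate_hz frame rate of the behavioral clock, Hz.
#' @param arena_cm optional `c(width, height)` used for a bounds warning.
#' @return a validated `track_table` data.frame.
#' @export
track_table <- function(frame, time_s, bee_id, x_cm, y_cm, theta_deg,
                        frame_rate_hz = 10, arena_cm = NULL) {
  df <- data.frame(frame = as.integer(frame), time_s = as.numeric(time_s),
                   bee_id = as.character(bee_id), x_cm = as.numeric(x_cm),
                   y_cm = as.numeric(y_cm),
                   theta_deg = as.numeric(theta_deg),
                   stringsAsFactors = FALSE)
  attr(df, "frame_rate_hz") <- frame_rate_hz
  attr(df, "arena_cm") <- arena_cm
  class(df) <- c("track_table", "data.frame")
  validate_track_table(df)
}

validate_track_table <- function(df) {
  req <- c("frame", "time_s", "bee_id", "x_cm", "y_cm", "theta_deg")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stopf("track table is missing columns: %s", paste(miss, collapse = ", "),
          class = "beesocial_io_error")
  }
  ids <- unique(df$bee_id)
  idnum <- match(df$bee_id, ids)
  key <- idnum * (max(df$frame) + 1) + df$frame
  dup <- anyDuplicated(key)
  if (dup) {
    stopf("duplicate (frame, bee_id) record at row %d: frame %d, bee '%s'",
          dup, df$frame[dup], df$bee_id[dup], class = "beesocial_io_error")
  }
  rate <- attr(df, "frame_rate_hz") %||% 10
  bad_t <- which(abs(df$time_s - df$frame / rate) > 1e-6)
  if (length(bad_t)) {
    stopf("time_s does not equal frame / frame_rate at row %d", bad_t[1],
          class = "beesocial_io_error")
  }
  by_bee <- split(df$frame, idnum)
  for (b in seq_along(by_bee)) {
    if (is.unsorted(by_bee[[b]], strictly = TRUE)) {
      stopf("frames are not strictly increasing for bee '%s'", ids[b],
            class = "beesocial_io_error")
    }
  }
  if (any(df$theta_deg < 0 | df$theta_deg >= 360, na.rm = TRUE)) {
    stopf("theta_deg must lie in [0, 360)", class = "beesocial_io_error")
  }
  arena <- attr(df, "arena_cm")
  if (!is.null(arena)) {
    out <- df$x_cm < 0 | df$x_cm > arena[1] | df$y_cm < 0 | df$y_cm > arena[2]
    if (any(out, na.rm = TRUE)) {
      warning(sprintf("%d track records fall outside the declared arena bounds",
                      sum(out, na.rm = TRUE)), call. = FALSE)
    }
  }
  df
}

#' Read and write tracking tables
#'
#' CSV with header `frame,time_s,bee_id,x_cm,y_cm,theta_deg`. Gzip-compressed
#' files (`.gz`) are read transparently. `read_tracks(write_tracks(x))`
#' reproduces `x` (coordinates are serialized at micrometer precision, which
#' is also the precision the generator emits).
#'
#' @param path CSV file path.
#' @param frame_rate_hz frame rate used to validate `time_s`.
#' @return `read_tracks()` returns a `track_table`; `write_tracks()` returns
#'   `path` invisibly.
#' @export
read_tracks <- function(path, frame_rate_hz = 10) {
  if (!file.exists(path)) stopf("tracks file not found: %s", path,
                                class = "beesocial_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "time_s", "bee_id", "x_cm", "y_cm", "theta_deg")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stopf("tracks file %s is missing columns: %s", path,
          paste(miss, collapse = ", "), class = "beesocial_io_error")
  }
  track_table(df$frame, df$time_s, df$bee_id, df$x_cm, df$y_cm, df$theta_deg,
              frame_rate_hz = frame_rate_hz)
}

#' @rdname read_tracks
#' @param tracks a `track_table`.
#' @export
write_tracks <- function(tracks, path) {
  validate_track_table(tracks)
  out <- data.frame(frame = tracks$frame,
                    time_s = sprintf("%.3f", tracks$time_s),
                    bee_id = tracks$bee_id,
                    x_cm = sprintf("%.6f", tracks$x_cm),
                    y_cm = sprintf("%.6f", tracks$y_cm),
                    theta_deg = sprintf("%.6f", tracks$theta_deg),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a spike train
#'
#' Sorted spike times, in seconds, of a single unit.
#'
#' @param times numeric spike times, s; must be non-decreasing.
#' @param unit unit label.
#' @param t_span optional recording span `c(t0, t1)`; spikes must fall inside.
#' @return a numeric vector of class `spike_train`.
#' @export
spike_train <- function(times, unit = "unit1", t_span = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) stopf("spike times contain NA", class = "beesocial_io_error")
  if (is.unsorted(times)) {
    stopf("spike times are not sorted ascending (sorting is the spike sorter's job)",
          class = "beesocial_io_error")
  }
  if (!is.null(t_span) && length(times) &&
      (times[1] < t_span[1] || times[length(times)] > t_span[2])) {
    stopf("spike times fall outside the recording span [%g, %g] s",
          t_span[1], t_span[2], class = "beesocial_io_error")
  }
  structure(times, unit = unit, t_span = t_span, class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit '%s', %d spikes", attr(x, "unit"), length(x)))
  if (length(x)) cat(sprintf(" on [%.3f, %.3f] s", x[1], x[length(x)]))
  cat("\n")
  invisible(x)
}

#' Read and write spike-time files
#'
#' Plain text, one spike time (seconds) per line, sorted ascending. An empty
#' file yields an empty train; an unsorted file is an error (a silent reorder
#' would hide upstream sorting bugs); a non-numeric line is a parse error
#' naming the line.
#'
#' @param path file path (plain or `.gz`).
#' @param unit unit label attached to the train.
#' @return `read_spikes()` returns a `spike_train`; `write_spikes()` returns
#'   `path` invisibly.
#' @export
read_spikes <- function(path, unit = "unit1") {
  if (!file.exists(path)) stopf("spikes file not found: %s", path,
                                class = "beesocial_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(spike_train(numeric(0), unit = unit))
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals))
  if (length(bad)) {
    stopf("non-numeric spike time at line %d of %s: '%s'",
          bad[1], path, lines[bad[1]], class = "beesocial_io_error")
  }
  spike_train(vals, unit = unit)
}

#' @rdname read_spikes
#' @param train a `spike_train`.
#' @export
write_spikes <- function(train, path) {
  writeLines(sprintf("%.6f", as.numeric(train)), path)
  invisible(path)
}

#' Bin spike times onto the behavioral clock
#'
#' Counts spikes in half-open bins `[t, t + bin_w)` starting at `t0`; a final
#' partial bin is dropped so that only whole bins are reported. The rate is
#' `count / bin_w`. With `t0` at a frame time and `bin_w` equal to the frame
#' period, bin edges coincide with the tracker's frame grid.
#'
#' @param train a `spike_train` (or numeric spike times).
#' @param t0,t1 span to bin, s (`t0 < t1`).
#' @param bin_w bin width, s (default 0.1 = 100 ms).
#' @return a `rate_series` data.frame with columns `t` (bin left edge, s),
#'   `count`, `rate` (Hz).
#' @export
bin_spikes <- function(train, t0, t1, bin_w = 0.1) {
  assert_scalar_num(bin_w, "bin_w", lower = 1e-9)
  if (!is.numeric(t0) || !is.numeric(t1) || t0 >= t1) {
    stopf("need t0 < t1", class = "beesocial_io_error")
  }
  n_bins <- floor((t1 - t0) / bin_w + 1e-9)
  times <- as.numeric(train)
  idx <- floor((times - t0) / bin_w) + 1
  idx <- idx[times >= t0 & idx >= 1 & idx <= n_bins]
  counts <- tabulate(idx, nbins = n_bins)
  out <- data.frame(t = t0 + (seq_len(n_bins) - 1) * bin_w,
                    count = counts, rate = counts / bin_w)
  attr(out, "bin_w") <- bin_w
  attr(out, "t0") <- t0
  class(out) <- c("rate_series", "data.frame")
  out
}
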