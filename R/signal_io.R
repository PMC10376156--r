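#' Low-pass Butterworth filter specification
#'
#' The workflow uses three cutoffs: 6 Hz for optical marker trajectories,
#' 10 Hz for insole and general IMU channels, and 2.3 Hz for the shank
#' mediolateral angular velocity used in gait-event detection. The filter
#' order is not dictated by the processing chain itself; order 4 applied
#' forward-backward (zero phase) is the gait-analysis standard and avoids
#' phase lag that would shift detected events.
#'
#' @param cutoff_hz low-pass cutoff frequency in Hz (must be below Nyquist).
#' @param order filter order (>= 1).
#' @param zero_phase apply the filter forward and backward (no phase lag).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(cutoff_hz, order = 4, zero_phase = TRUE) {
  stopifnot(is.numeric(cutoff_hz), cutoff_hz > 0, order >= 1)
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Zero-phase low-pass filtering
#'
#' Applies a Butterworth low-pass filter designed by [signal::butter()]. With
#' `zero_phase = TRUE` the filter runs forward and backward over the series;
#' the input is extended by odd reflection at both ends (three filter lengths)
#' before filtering so that constants and linear ramps pass through unchanged
#' and start-up transients do not leak into the output.
#'
#' @param series numeric vector (one channel).
#' @param fs sampling frequency of `series` in Hz.
#' @param spec a [filter_spec()].
#' @return Filtered numeric vector of the same length as `series`.
#' @examples
#' x <- sin(2 * pi * 1 * sample_times(2, 128))
#' y <- lowpass(x, 128, filter_spec(10))
#' max(abs(x - y)) < 0.05
#' @export
lowpass <- function(series, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff_hz >= fs / 2)
    stop("filter cutoff must be below the Nyquist frequency fs/2")
  n <- length(series)
  if (n <= 3 * spec$order)
    stop("series too short for the requested filter order")
  bf <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  if (!spec$zero_phase) return(as.numeric(signal::filter(bf, series)))
  # anchor a line through the endpoints and filter the residual: constants
  # and linear ramps pass through exactly, and edge transients shrink
  line <- series[1] + (series[n] - series[1]) * (seq_len(n) - 1) / (n - 1)
  r <- series - line
  npad <- min(n - 1L, max(3L * 3L * spec$order, 24L))
  # odd (point-symmetric) reflection stabilizes the ends
  head_pad <- 2 * r[1] - r[(npad + 1):2]
  tail_pad <- 2 * r[n] - r[(n - 1):(n - npad)]
  x <- c(head_pad, r, tail_pad)
  fwd <- signal::filter(bf, x)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(fwd)))))
  y[(npad + 1):(npad + n)] + line
}

#' Resample a series onto a new uniform rate
#'
#' Linear interpolation onto a uniform `fs_out` grid spanning the same time
#' interval as the input; the output has `floor((N - 1) * fs_out / fs_in) + 1`
#' samples. Used to bring the 100 Hz insole force onto the 128 Hz IMU clock.
#'
#' @param series numeric vector sampled uniformly at `fs_in`.
#' @param fs_in,fs_out input and output sampling frequencies in Hz.
#' @return Numeric vector on the `fs_out` grid.
#' @examples
#' length(resample_to(rep(1, 100), 100, 128))  # 1 s of data -> 128 samples
#' @export
resample_to <- function(series, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  n <- length(series)
  if (n < 2) stop("need at least 2 samples to resample")
  if (fs_in == fs_out) return(series)
  t_in <- (seq_len(n) - 1) / fs_in
  n_out <- floor((n - 1) * fs_out / fs_in) + 1
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, series, xout = t_out, rule = 2)$y
}

#' Re-align a shank IMU to the pure lateral mounting position
#'
#' IMUs strapped to the anteromedial shank are rotated about the segment's
#' longitudinal axis back to the pure lateral position before event
#' detection, using the goniometrically captured mounting angle (cohort mean
#' 121.3 degrees). A positive angle carries the sensor anterior axis toward
#' the lateral axis; vector channels (acceleration, angular velocity,
#' magnetic field) are rotated, and the orientation quaternion is composed
#' with the same axis rotation so that the stream stays internally
#' consistent.
#'
#' @param stream an [imu_stream()] with `segment = "shank"`.
#' @param angle_deg rotation angle in degrees about the longitudinal axis.
#' @return The rotated `imu_stream`.
#' @export
rotate_shank_imu <- function(stream, angle_deg = 121.3) {
  stopifnot(inherits(stream, "imu_stream"))
  if (stream$segment != "shank")
    stop("rotate_shank_imu is defined for shank-mounted streams")
  a <- angle_deg * pi / 180
  R <- rot_long(a)
  out <- stream
  for (nm in c("acc", "gyro", "mag"))
    out[[nm]] <- stream[[nm]] %*% t(R)
  # channel vectors transform with R, so the sensor basis rotates with R^T:
  # q_new = q_old (x) quat(R^T)
  q_rot <- quat_from_matrix(t(R))
  qn <- quat_multiply(stream$quat, q_rot)
  out$quat <- qn / sqrt(rowSums(qn^2))
  out
}

# ---------------------------------------------------------------------------
# Delimited-text schemas
# ---------------------------------------------------------------------------

.schema_cols <- list(
  imu = c("t", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z",
          "mag_x", "mag_y", "mag_z", "quat_w", "quat_x", "quat_y", "quat_z"),
  insole = c("t", "grf_v"),
  marker = c("t", "pos_x", "pos_y", "pos_z")
)

#' Read and write sensor streams as delimited text
#'
#' Streams are stored as comma-separated files with a header row and one
#' leading comment line `# stairgait <schema> key=value ...` recording the
#' sampling frequency and (for IMUs) the segment label. Columns: IMU `t,
#' acc_x/y/z, gyr_x/y/z, mag_x/y/z, quat_w/x/y/z` (m/s^2, rad/s, a.u., unit
#' quaternion scalar-first); insole `t, grf_v` (N); marker `t, pos_x/y/z`
#' (m, lab frame). Missing samples (`NA`) are linearly interpolated when the
#' gap is at most 0.1 s; longer dropouts are an error.
#'
#' @param path file path.
#' @param schema one of `"imu"`, `"insole"`, `"marker"`.
#' @param segment segment label used if the file carries none (IMU only).
#' @param fs sampling frequency used if the file carries none; otherwise
#'   inferred from the metadata line (or the median time step).
#' @return `read_stream()` returns an [imu_stream()], [insole_stream()] or
#'   [marker_trace()]; `write_stream()` returns `path` invisibly.
#' @export
read_stream <- function(path, schema = c("imu", "insole", "marker"),
                        segment = NULL, fs = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  meta <- list()
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
    for (item in kv) {
      p <- strsplit(item, "=", fixed = TRUE)[[1]]
      meta[[p[1]]] <- p[2]
    }
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  want <- .schema_cols[[schema]]
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("schema error: file lacks column(s) %s",
                 paste(missing_cols, collapse = ", ")))
  df <- df[want]
  if (is.null(fs)) {
    fs <- if (!is.null(meta$fs)) as.numeric(meta$fs)
          else 1 / stats::median(diff(df$t))
  }
  for (j in seq_along(df)[-1])
    df[[j]] <- fill_short_gaps(df[[j]], fs, max_gap_s = 0.1)
  if (schema == "imu") {
    seg <- segment %||% meta$segment
    if (is.null(seg)) stop("IMU file carries no segment label; pass `segment`")
    imu_stream(df$t,
               acc = as.matrix(df[, 2:4]), gyro = as.matrix(df[, 5:7]),
               mag = as.matrix(df[, 8:10]), quat = as.matrix(df[, 11:14]),
               fs = fs, segment = seg)
  } else if (schema == "insole") {
    insole_stream(df$t, df$grf_v, fs = fs)
  } else {
    marker_trace(df$t, as.matrix(df[, 2:4]), fs = fs,
                 name = meta$name %||% "heel")
  }
}

#' @param x a stream object to write.
#' @rdname read_stream
#' @export
write_stream <- function(x, path) {
  if (inherits(x, "imu_stream")) {
    hdr <- sprintf("# stairgait imu segment=%s fs=%g", x$segment, x$fs)
    df <- data.frame(x$t, x$acc, x$gyro, x$mag, x$quat)
    names(df) <- .schema_cols$imu
  } else if (inherits(x, "insole_stream")) {
    hdr <- sprintf("# stairgait insole fs=%g", x$fs)
    df <- data.frame(t = x$t, grf_v = x$grf_v)
  } else if (inherits(x, "marker_trace")) {
    hdr <- sprintf("# stairgait marker name=%s fs=%g", x$name, x$fs)
    df <- data.frame(x$t, x$pos)
    names(df) <- .schema_cols$marker
  } else stop("unsupported stream object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

fill_short_gaps <- function(x, fs, max_gap_s = 0.1) {
  if (!anyNA(x)) return(as.numeric(x))
  r <- rle(is.na(x))
  if (any(r$lengths[r$values] > max_gap_s * fs))
    stop(sprintf("dropout longer than %g s cannot be interpolated", max_gap_s))
  idx <- which(!is.na(x))
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
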