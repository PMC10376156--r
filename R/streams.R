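#' Sensor stream containers
#'
#' `imu_stream()`, `insole_stream()` and `marker_trace()` build the three
#' validated time-series containers used throughout the package. All streams
#' carry a uniform time base `t` (seconds) sampled at `fs` Hz; channel data
#' are stored samples-by-channels.
#'
#' Frame conventions (fixed package-wide): lab x = anteroposterior (anterior
#' positive), y = vertical (up positive), z = mediolateral (lateral positive
#' for the instrumented right leg). IMU sensor axes: x anterior, y
#' longitudinal (proximal), z lateral. Quaternions are scalar-first Hamilton
#' quaternions mapping sensor-frame coordinates to lab-frame coordinates.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing
#'   with step `1/fs` (1% jitter tolerated).
#' @param acc,gyro,mag N x 3 matrices: linear acceleration (m/s^2), angular
#'   velocity (rad/s) and magnetic field (arbitrary units) in sensor axes.
#' @param quat N x 4 matrix of unit quaternions, scalar first.
#' @param fs sampling frequency in Hz.
#' @param segment `"shank"` or `"thigh"`.
#' @return An object of class `imu_stream`, `insole_stream` or
#'   `marker_trace`: a list with the validated fields above.
#' @examples
#' n <- 16
#' q <- cbind(rep(1, n), 0, 0, 0)
#' s <- imu_stream(t = (0:(n - 1)) / 128, acc = matrix(0, n, 3),
#'                 gyro = matrix(0, n, 3), mag = matrix(0, n, 3),
#'                 quat = q, fs = 128, segment = "shank")
#' s$fs
#' @export
imu_stream <- function(t, acc, gyro, mag, quat, fs, segment = c("shank", "thigh")) {
  segment <- match.arg(segment)
  t <- as.numeric(t)
  acc <- as_channels(acc, 3, "acc")
  gyro <- as_channels(gyro, 3, "gyro")
  mag <- as_channels(mag, 3, "mag")
  quat <- as_channels(quat, 4, "quat")
  n <- length(t)
  for (nm in c("acc", "gyro", "mag", "quat")) {
    ch <- get(nm)
    if (nrow(ch) != n)
      stop(sprintf("channel '%s' has %d samples, expected %d", nm, nrow(ch), n))
  }
  check_uniform_time(t, fs)
  qn <- sqrt(rowSums(quat^2))
  if (any(abs(qn - 1) > 1e-6))
    stop("quaternion rows must have unit norm (tolerance 1e-6)")
  structure(list(t = t, acc = acc, gyro = gyro, mag = mag, quat = quat,
                 fs = fs, segment = segment),
            class = "imu_stream")
}

#' @param grf_v numeric vector of vertical ground reaction force in newtons;
#'   negative readings are clamped to zero.
#' @rdname imu_stream
#' @export
insole_stream <- function(t, grf_v, fs) {
  t <- as.numeric(t)
  grf_v <- pmax(as.numeric(grf_v), 0)
  if (length(grf_v) != length(t))
    stop("grf_v and t must have the same length")
  check_uniform_time(t, fs)
  structure(list(t = t, grf_v = grf_v, fs = fs), class = "insole_stream")
}

#' @param pos N x 3 matrix of marker position (m) in the lab frame.
#' @param name marker label.
#' @rdname imu_stream
#' @export
marker_trace <- function(t, pos, fs, name = "heel") {
  t <- as.numeric(t)
  pos <- as_channels(pos, 3, "pos")
  if (nrow(pos) != length(t)) stop("pos and t must have the same length")
  check_uniform_time(t, fs)
  if (any(!is.finite(pos))) stop("marker positions must be finite after gap interpolation")
  structure(list(t = t, pos = pos, fs = fs, name = name), class = "marker_trace")
}

as_channels <- function(x, k, nm) {
  x <- as.matrix(x)
  if (ncol(x) != k) stop(sprintf("'%s' must have %d columns", nm, k))
  storage.mode(x) <- "double"
  x
}

check_uniform_time <- function(t, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (length(t) >= 2) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("time stamps must be strictly increasing")
    if (any(abs(dt - 1 / fs) > 0.01 / fs))
      stop("non-uniform time stamps: jitter exceeds 1% of the sample period")
  }
  invisible(TRUE)
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> segment=%s fs=%g Hz n=%d span=[%.3f, %.3f] s\n",
              x$segment, x$fs, length(x$t), x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' @export
print.insole_stream <- function(x, ...) {
  cat(sprintf("<insole_stream> fs=%g Hz n=%d peak=%.1f N\n",
              x$fs, length(x$t), max(x$grf_v)))
  invisible(x)
}

#' @export
print.marker_trace <- function(x, ...) {
  cat(sprintf("<marker_trace> '%s' fs=%g Hz n=%d\n", x$name, x$fs, length(x$t)))
  invisible(x)
}

#' Uniform sample-time grid
#'
#' Time stamps for a recording of `duration` seconds at `fs` Hz, starting at
#' `t0`. A 30 s stream at 128 Hz has exactly `30 * 128 = 3840` samples.
#'
#' @param duration length of the recording in seconds.
#' @param fs sampling frequency in Hz.
#' @param t0 time of the first sample in seconds.
#' @return Numeric vector of `round(duration * fs)` sample times.
#' @examples
#' length(sample_times(30, 128))
#' @export
sample_times <- function(duration, fs, t0 = 0) {
  n <- round(duration * fs)
  t0 + (seq_len(n) - 1) / fs
}
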