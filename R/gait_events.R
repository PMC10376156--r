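#' Gait-event container
#'
#' Heel-strike and toe-off times plus the per-cycle stance fractions derived
#' from them. A complete cycle is a heel strike, the following toe off, and
#' the next heel strike; incomplete leading/trailing cycles are dropped by
#' the constructors.
#'
#' @param hs_times heel-strike times in seconds, strictly increasing.
#' @param to_times toe-off times in seconds; each must lie strictly between
#'   consecutive heel strikes.
#' @return A `gait_events` list with fields `hs_times`, `to_times`,
#'   `stance_fraction` (one value per complete cycle) and `n_cycles`.
#' @export
gait_events <- function(hs_times, to_times) {
  hs_times <- as.numeric(hs_times)
  to_times <- as.numeric(to_times)
  if (is.unsorted(hs_times, strictly = TRUE))
    stop("heel-strike times must be strictly increasing")
  n_cycles <- max(length(hs_times) - 1L, 0L)
  stance <- rep(NA_real_, n_cycles)
  if (n_cycles > 0) {
    for (i in seq_len(n_cycles)) {
      to_i <- to_times[to_times > hs_times[i] & to_times < hs_times[i + 1]]
      if (length(to_i) != 1)
        stop("event-sequence error: expected exactly one toe off per cycle")
      stance[i] <- (to_i - hs_times[i]) / (hs_times[i + 1] - hs_times[i])
    }
    if (any(stance <= 0 | stance >= 1))
      stop("stance fraction must lie strictly in (0, 1)")
  }
  structure(list(hs_times = hs_times, to_times = to_times,
                 stance_fraction = stance, n_cycles = n_cycles),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d complete cycle(s); mean stance %.1f%%\n",
              x$n_cycles,
              if (x$n_cycles) mean(x$stance_fraction) * 100 else NA_real_))
  invisible(x)
}

#' Heel-strike detection from the optical heel marker
#'
#' Heel strike is the instant the anteroposterior (AP) velocity of the heel
#' marker returns to 0 m/s immediately after the swing phase. Swing is
#' identified as a contiguous interval with AP velocity above
#' `swing_threshold` sustained for at least `min_swing_s`; the first downward
#' zero crossing at or after the end of each such interval is reported. The
#' trace is expected to be low-pass filtered at 6 Hz beforehand.
#'
#' @param heel a [marker_trace()] (AP = x component).
#' @param swing_threshold AP velocity (m/s) that defines swing; 0.2 m/s is
#'   robust for stair ascent, where swing speeds exceed 1 m/s.
#' @param min_swing_s minimum swing duration in seconds.
#' @return Numeric vector of heel-strike times (possibly empty).
#' @export
detect_hs_mocap <- function(heel, swing_threshold = 0.2, min_swing_s = 0.1) {
  stopifnot(inherits(heel, "marker_trace"))
  v <- central_diff(heel$pos[, 1], heel$fs)
  n <- length(v)
  swing <- v > swing_threshold
  r <- rle(swing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths >= min_swing_s * heel$fs)
  hs <- numeric(0)
  for (k in which(keep)) {
    i <- ends[k]
    # first downward zero crossing at/after the swing run
    while (i < n && !(v[i] > 0 && v[i + 1] <= 0)) i <- i + 1
    if (i < n) {
      # linear interpolation of the crossing instant
      frac <- v[i] / (v[i] - v[i + 1])
      hs <- c(hs, heel$t[i] + frac / heel$fs)
    }
  }
  unique(hs)
}

#' Gait events from the instrumented insole (20 N threshold)
#'
#' Heel strike occurs when the vertical ground reaction force exceeds
#' `threshold` newtons with a positive slope; toe off when it descends back
#' below the same threshold. These insole events define each gait cycle's
#' percentages. The force is expected to be low-pass filtered at 10 Hz
#' beforehand; crossings are taken at the first sample beyond the threshold
#' (earliest sample wins on ties).
#'
#' @param insole an [insole_stream()].
#' @param threshold force threshold in newtons (field standard 20 N).
#' @return A [gait_events()] object.
#' @export
detect_events_insole <- function(insole, threshold = 20) {
  stopifnot(inherits(insole, "insole_stream"))
  y <- insole$grf_v
  n <- length(y)
  if (n < 2) return(gait_events(numeric(0), numeric(0)))
  up <- which(y[-n] <= threshold & y[-1] > threshold) + 1L
  dn <- which(y[-n] >= threshold & y[-1] < threshold) + 1L
  hs <- insole$t[up]
  to <- insole$t[dn]
  # drop a leading toe off (recording may start mid-stance)
  if (length(hs) == 0) return(gait_events(numeric(0), numeric(0)))
  to <- to[to > hs[1]]
  ev <- sort(c(hs, to))
  lab <- c(rep("hs", length(hs)), rep("to", length(to)))[order(c(hs, to))]
  if (any(lab[-1] == lab[-length(lab)]))
    stop("event-sequence error: threshold crossings do not alternate")
  gait_events(hs, to)
}

#' Heel-strike detection from the shank IMU
#'
#' Heel strike is the first of the two local minima of the shank's
#' mediolateral-axis angular velocity during the stance phase. Candidate
#' stance regions are taken either from insole stance windows (when
#' `events` is supplied) or between successive swing peaks of the gyro
#' signal, which bracket stance. The mediolateral gyro channel is expected
#' to be low-pass filtered at 2.3 Hz beforehand (the shank stream already
#' rotated to the pure lateral position).
#'
#' @param shank an [imu_stream()] with `segment = "shank"`.
#' @param events optional [gait_events()] from the insole; if given, stance
#'   windows replace the gyro-peak bracketing.
#' @param peak_frac fraction of the global gyro maximum a local maximum must
#'   reach to count as a swing peak.
#' @param min_separation_s minimum separation between swing peaks in seconds.
#' @return Numeric vector of heel-strike times; regions with fewer than two
#'   local minima are skipped with a message.
#' @export
detect_hs_imu <- function(shank, events = NULL, peak_frac = 0.5,
                          min_separation_s = 0.5) {
  stopifnot(inherits(shank, "imu_stream"))
  w <- shank$gyro[, 3]
  t <- shank$t
  n <- length(w)
  if (n < 3 || diff(range(w)) < sqrt(.Machine$double.eps)) return(numeric(0))
  regions <- if (!is.null(events) && events$n_cycles > 0) {
    cbind(events$hs_times[-length(events$hs_times)] - 0.05, events$to_times)
  } else {
    pk <- local_extrema(w, "max")
    pk <- pk[w[pk] > peak_frac * max(w)]
    pk <- thin_peaks(pk, w, min_separation_s * shank$fs)
    if (length(pk) < 2) return(numeric(0))
    cbind(t[pk[-length(pk)]], t[pk[-1]])
  }
  mins <- local_extrema(w, "min")
  hs <- numeric(0)
  for (k in seq_len(nrow(regions))) {
    in_reg <- mins[t[mins] > regions[k, 1] & t[mins] < regions[k, 2]]
    if (length(in_reg) < 2) {
      message(sprintf("detect_hs_imu: region %d has %d local minima; skipped",
                      k, length(in_reg)))
      next
    }
    two <- in_reg[order(w[in_reg])[1:2]]  # the two deepest
    hs <- c(hs, t[min(two)])              # first of the two
  }
  sort(hs)
}

local_extrema <- function(x, what = c("min", "max")) {
  what <- match.arg(what)
  d <- diff(x)
  if (what == "min") which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  else which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
}

thin_peaks <- function(idx, x, min_gap) {
  if (length(idx) < 2) return(idx)
  keep <- idx[1]
  for (i in idx[-1]) {
    if (i - keep[length(keep)] < min_gap) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  keep
}

central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 3) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

#' Temporal synchronization of the sensing modalities
#'
#' Each stream is shifted in time so that its own first heel strike aligns
#' with the optical-capture heel strike, then all streams are cropped to the
#' common overlapping interval. After synchronization the first heel strikes
#' coincide within half a sample period.
#'
#' @param mocap_hs first heel-strike time from the heel marker (s).
#' @param imu shank [imu_stream()].
#' @param insole [insole_stream()].
#' @param imu_hs,insole_hs first heel-strike times detected on the IMU and
#'   insole streams (s, in each stream's own clock).
#' @param extra_imu optional second IMU sharing the first IMU's clock (the
#'   thigh unit); it is shifted by the same lag.
#' @return List with elements `imu`, `insole` and (if given) `extra_imu`.
#' @export
synchronize <- function(mocap_hs, imu, insole, imu_hs, insole_hs,
                        extra_imu = NULL) {
  stopifnot(is.finite(mocap_hs), is.finite(imu_hs), is.finite(insole_hs))
  imu <- shift_stream(imu, mocap_hs - imu_hs)
  insole <- shift_stream(insole, mocap_hs - insole_hs)
  if (!is.null(extra_imu))
    extra_imu <- shift_stream(extra_imu, mocap_hs - imu_hs)
  streams <- c(list(imu, insole), if (!is.null(extra_imu)) list(extra_imu))
  lo <- max(vapply(streams, function(s) s$t[1], 0))
  hi <- min(vapply(streams, function(s) s$t[length(s$t)], 0))
  if (hi - lo <= 0)
    stop("synchronization error: streams do not overlap after shifting")
  out <- lapply(streams, crop_stream, lo = lo, hi = hi)
  names(out) <- c("imu", "insole", if (!is.null(extra_imu)) "extra_imu")
  out
}

shift_stream <- function(s, lag) { s$t <- s$t + lag; s }

crop_stream <- function(s, lo, hi) {
  keep <- s$t >= lo - 1e-9 & s$t <= hi + 1e-9
  s$t <- s$t[keep]
  for (nm in intersect(names(s), c("acc", "gyro", "mag", "quat", "pos")))
    s[[nm]] <- s[[nm]][keep, , drop = FALSE]
  if ("grf_v" %in% names(s)) s$grf_v <- s$grf_v[keep]
  s
}

#' Time-normalization of a signal to gait percent
#'
#' Each complete heel-strike-to-heel-strike cycle is linearly resampled to
#' `n_points` samples spanning 0-100% of the gait cycle inclusive. The
#' 101-point vector is the field convention and makes 0/30/60/80% exact grid
#' points.
#'
#' @param series numeric vector sampled uniformly at `fs`.
#' @param fs sampling frequency of `series` in Hz.
#' @param events a [gait_events()] object (times in the same clock as
#'   `series`, whose first sample is at `t0`).
#' @param n_points samples per normalized cycle (default 101).
#' @param t0 time of the first sample of `series`.
#' @param metric_name,units stored as attributes on the result.
#' @return A `cycle_matrix`: `n_cycles x n_points` numeric matrix, one row
#'   per complete cycle.
#' @export
normalize_to_gait_percent <- function(series, fs, events, n_points = 101,
                                      t0 = 0, metric_name = "signal",
                                      units = "") {
  if (events$n_cycles < 1)
    stop("no complete gait cycle available for normalization")
  t <- t0 + (seq_along(series) - 1) / fs
  rows <- matrix(NA_real_, events$n_cycles, n_points)
  for (i in seq_len(events$n_cycles)) {
    tt <- seq(events$hs_times[i], events$hs_times[i + 1], length.out = n_points)
    rows[i, ] <- stats::approx(t, series, xout = tt, rule = 2)$y
  }
  structure(rows, class = c("cycle_matrix", "matrix"),
            metric_name = metric_name, units = units,
            percent = seq(0, 100, length.out = n_points))
}

#' Ensemble average over gait cycles or subjects
#'
#' Pointwise mean and sample standard deviation at each gait percent.
#'
#' @param cycles a `cycle_matrix` (or any rows-by-percent numeric matrix).
#' @return List with numeric vectors `mean` and `sd` (length `ncol(cycles)`).
#' @export
ensemble_average <- function(cycles) {
  stopifnot(is.matrix(cycles), nrow(cycles) >= 1)
  list(mean = colMeans(cycles),
       sd = apply(cycles, 2, stats::sd))
}

#' Write detected events as delimited text
#'
#' One row per complete cycle: `cycle_index, hs_time_s, to_time_s,
#' stance_fraction`.
#'
#' @param events a [gait_events()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(cycle_index = seq_len(events$n_cycles),
                   hs_time_s = events$hs_times[seq_len(events$n_cycles)],
                   to_time_s = events$to_times[seq_len(events$n_cycles)],
                   stance_fraction = events$stance_fraction)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
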