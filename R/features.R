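#' Pre-process one trial and assemble the ANN feature matrix
#'
#' Runs the full wearable pre-processing chain on a [generate_trial()]
#' record (or an equivalent object built from files):
#'
#' 1. low-pass filter insole force at 10 Hz and resample 100 -> 128 Hz;
#' 2. low-pass filter all IMU channels at 10 Hz (quaternions re-normalized),
#'    keeping a 2.3 Hz copy of the shank mediolateral gyro for event
#'    detection;
#' 3. rotate the shank IMU to the pure lateral position (121.3 deg);
#' 4. low-pass filter the heel marker at 6 Hz and detect the optical heel
#'    strike; detect insole and IMU heel strikes;
#' 5. shift every stream so first heel strikes align with the optical one
#'    and crop to the common interval;
#' 6. interpolate all channels onto the common 128 Hz grid and build the
#'    28-column feature matrix: 13 shank-IMU channels, 13 thigh-IMU
#'    channels, vertical GRF, and the activity duration (trial length,
#'    replicated); targets are the four ground-truth curves.
#'
#' @param trial a `trial_record`.
#' @param mount_angle_deg shank re-alignment angle (degrees).
#' @return List with `X` (n x 28), `Y` (n x 4, columns `sag_angle`,
#'   `front_angle`, `sag_moment`, `front_moment`), `t`, `fs`, and `events`
#'   (insole [gait_events()] on the synchronized clock).
#' @export
build_features <- function(trial, mount_angle_deg = 121.3) {
  fs <- trial$imu_shank$fs

  ## insole: filter at 10 Hz, resample onto the IMU rate
  ins <- trial$insole
  grf_f <- lowpass(ins$grf_v, ins$fs, filter_spec(10))
  grf_rs <- resample_to(grf_f, ins$fs, fs)
  ins128 <- insole_stream(ins$t[1] + (seq_along(grf_rs) - 1) / fs,
                          pmax(grf_rs, 0), fs = fs)

  ## IMUs: 10 Hz channel filtering, shank re-alignment
  filt_imu <- function(s) {
    for (nm in c("acc", "gyro", "mag", "quat"))
      s[[nm]] <- apply(s[[nm]], 2, lowpass, fs = s$fs, spec = filter_spec(10))
    s$quat <- s$quat / sqrt(rowSums(s$quat^2))
    s
  }
  shank <- rotate_shank_imu(filt_imu(trial$imu_shank), mount_angle_deg)
  thigh <- filt_imu(trial$imu_thigh)
  shank_ev <- shank
  shank_ev$gyro[, 3] <- lowpass(shank$gyro[, 3], shank$fs, filter_spec(2.3))

  ## events per modality
  heel <- trial$heel
  heel$pos <- apply(heel$pos, 2, lowpass, fs = heel$fs, spec = filter_spec(6))
  hs_mocap <- detect_hs_mocap(heel)
  if (length(hs_mocap) == 0) stop("no optical heel strike found")
  ev_ins <- detect_events_insole(ins128)
  hs_imu <- detect_hs_imu(shank_ev)
  if (length(hs_imu) == 0) stop("no IMU heel strike found")

  ## synchronize to the optical heel strike and crop
  sync <- synchronize(hs_mocap[1], shank, ins128,
                      imu_hs = hs_imu[1], insole_hs = ev_ins$hs_times[1],
                      extra_imu = thigh)
  shank <- sync$imu; ins128 <- sync$insole; thigh <- sync$extra_imu

  ## common grid = synchronized shank grid
  tg <- shank$t
  interp_mat <- function(m, t_in) apply(m, 2, function(col)
    stats::approx(t_in, col, xout = tg, rule = 2)$y)
  imu_block <- function(s) cbind(interp_mat(s$acc, s$t),
                                 interp_mat(s$gyro, s$t),
                                 interp_mat(s$mag, s$t),
                                 interp_mat(s$quat, s$t))
  grf_g <- stats::approx(ins128$t, ins128$grf_v, xout = tg, rule = 2)$y
  duration <- tg[length(tg)] - tg[1]
  X <- cbind(imu_block(shank), imu_block(thigh), grf_g, duration)
  colnames(X) <- c(paste0("shank_", .imu_channel_names),
                   paste0("thigh_", .imu_channel_names),
                   "grf_v", "duration")

  Y <- vapply(c("sag_angle", "front_angle", "sag_moment", "front_moment"),
              function(nm) stats::approx(trial$truth$t, trial$truth[[nm]],
                                         xout = tg, rule = 2)$y,
              numeric(length(tg)))

  ev_sync <- detect_events_insole(ins128)
  list(X = X, Y = Y, t = tg, fs = fs, events = ev_sync)
}

.imu_channel_names <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z",
                        "mag_x", "mag_y", "mag_z",
                        "quat_w", "quat_x", "quat_y", "quat_z")
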