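#' Default sensor noise levels
#'
#' Additive white-noise SDs for the virtual sensors, small relative to the
#' signal ranges and consistent with consumer-grade hardware: gyroscope
#' 0.02 rad/s, accelerometer 0.2 m/s^2, magnetometer 0.05 a.u., quaternion
#' 0.002 (renormalized), insole force 5 N, marker position 0.3 mm (typical
#' optical-capture residual).
#'
#' @return Named list of noise SDs.
#' @export
default_noise <- function() {
  list(gyro = 0.02, acc = 0.2, mag = 0.05, quat = 0.002,
       grf = 5, marker = 3e-4)
}

#' @rdname default_noise
#' @export
zero_noise <- function() {
  list(gyro = 0, acc = 0, mag = 0, quat = 0, grf = 0, marker = 0)
}

#' Generate one synthetic stair-ascent trial
#'
#' Builds a fully synchronized multi-modal trial for one subject: jittered
#' ground-truth angle/moment curves on a 128 Hz time base, virtual shank and
#' thigh IMUs (the shank unit mounted 121.3 degrees from pure lateral),
#' a 100 Hz insole force stream, and a heel marker trace from forward
#' kinematics. Recording starts just after a toe off (gait phase 68%), so
#' the first heel strike is a detectable event on every modality; the trial
#' spans `n_cycles + 1` heel strikes, i.e. `n_cycles` complete insole-defined
#' cycles, plus a swing tail.
#'
#' Per-subject variability (drawn once per trial from the template SDs):
#' multiplicative amplitude scale and additive offset per output curve, mean
#' cycle duration, and stance fraction; each cycle's duration is further
#' jittered. The ground-truth moment curves are template-defined rather than
#' re-derived from the synthetic GRF by inverse dynamics, so the printed
#' calibration peaks are matched exactly; dynamic consistency of the
#' inverse-dynamics surrogate is validated separately.
#'
#' @param subj a [subject()].
#' @param templates a [default_templates()] object.
#' @param n_cycles number of complete gait cycles.
#' @param noise noise list as in [default_noise()].
#' @param seed integer seed controlling every random draw in the trial.
#' @param lags length-2 numeric `c(imu, insole)` clock offsets in seconds,
#'   or `NULL` to draw them uniformly from (-0.4, 0.4).
#' @param fs_imu,fs_insole sampling frequencies (Hz).
#' @return A `trial_record`: list with `subject`, streams (`imu_shank`,
#'   `imu_thigh`, `insole`, `heel`), `truth` (time base, four output curves,
#'   event times, gait phase) and `meta` (seed, noise, lags, mount angle).
#' @export
generate_trial <- function(subj, templates = default_templates(),
                           n_cycles = 5, noise = default_noise(),
                           seed = NULL, lags = NULL,
                           fs_imu = 128, fs_insole = 100) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(templates, "gait_templates"), n_cycles >= 1)

  ## per-subject curve calibration: one amplitude and one offset z-score per
  ## plane, shared between the angle and the moment of that plane. Sharing
  ## keeps the per-subject moment variability recoverable from the motion
  ## the sensors record (larger excursions go with larger moments), so the
  ## wearable record determines the targets up to sensor noise -- real
  ## cohorts also carry moment variability that kinematics cannot explain,
  ## which this generator deliberately omits.
  z_amp <- stats::rnorm(2)
  z_off <- stats::rnorm(2)
  k_sag <- 1 + templates$subject_scale_sd * z_amp[1]
  k_front <- 1 + templates$subject_scale_sd * z_amp[2]
  k_msag <- k_sag
  k_mfront <- k_front
  # the shank curve shares the sagittal amplitude scale so the heel-strike
  # velocity cancellation built into the templates survives subject scaling
  k_shank <- k_sag
  b_sag <- templates$angle_offset_sd_deg * z_off[1]
  b_front <- templates$angle_offset_sd_deg * z_off[2]
  b_msag <- templates$moment_offset_sd * z_off[1]
  b_mfront <- templates$moment_offset_sd * z_off[2]
  T_mean <- max(1.2, stats::rnorm(1, templates$cycle_duration_s,
                                  templates$cycle_duration_sd_s))
  stance <- min(0.80, max(0.55,
                          stats::rnorm(1, templates$stance_fraction,
                                       templates$stance_fraction_sd)))
  ## the subject's amplitude scale/offset perturb the heel-strike velocity
  ## cancellation built into the hip template (the segment cosines change);
  ## restore it with a localized hip slope correction at the cycle boundary
  hip0 <- k_sag * templates$sag_angle(0) + b_sag
  shank0 <- k_shank * templates$shank_angle(0)
  shank_slope0 <- k_shank *
    (templates$shank_angle(0.01) - templates$shank_angle(99.99)) / 0.02
  hip_slope0 <- k_sag *
    (templates$sag_angle(0.01) - templates$sag_angle(99.99)) / 0.02
  c_corr <- hip_slope_for_heel_zero(hip0, shank0, templates$ankle_angle(0),
                                    shank_slope0) - hip_slope0

  ## note: the angle/moment templates keep their fixed cycle structure
  ## (toe off near 67%) while the insole stance window follows the
  ## subject's drawn stance fraction; retiming the curves to each subject's
  ## toe off was tried and rejected because it displaces the shank-gyro
  ## heel-strike signature that the IMU event detector relies on
  curves <- list(
    sag_angle = function(p) k_sag * templates$sag_angle(p) + b_sag +
      c_corr * local_slope_at0(p),
    front_angle = function(p) k_front * templates$front_angle(p) + b_front,
    sag_moment = function(p) k_msag * templates$sag_moment(p) + b_msag,
    front_moment = function(p) k_mfront * templates$front_moment(p) + b_mfront,
    shank_angle = function(p) k_shank * templates$shank_angle(p),
    ankle_angle = templates$ankle_angle)

  ## cycle schedule: phase anchors (percent) against time, starting at 68%
  n_hs <- n_cycles + 1L
  T_i <- T_mean * pmax(0.8, stats::rnorm(n_hs + 1L, 1, templates$cycle_jitter_sd))
  lead <- 0.32 * T_i[1]
  tail <- 0.69 * T_i[n_hs + 1L]
  anchor_t <- cumsum(c(0, lead, T_i[2:n_hs], tail))
  anchor_p <- c(68, seq(100, by = 100, length.out = n_hs), n_hs * 100 + 69)
  duration <- anchor_t[length(anchor_t)]
  hs_times <- anchor_t[2:(n_hs + 1L)]
  phase_at <- function(tt) stats::approx(anchor_t, anchor_p, xout = tt,
                                         rule = 2)$y

  t_imu <- sample_times(duration, fs_imu)
  phi <- phase_at(t_imu)

  truth <- list(
    t = t_imu, fs = fs_imu,
    sag_angle = curves$sag_angle(phi),
    front_angle = curves$front_angle(phi),
    sag_moment = curves$sag_moment(phi),
    front_moment = curves$front_moment(phi),
    hs_times = hs_times,
    # toe off inside each complete cycle at the subject stance fraction
    to_times = hs_times[-n_hs] + stance * diff(hs_times),
    stance_fraction = stance,
    phase = phi)

  ## kinematic chain and virtual sensors
  shank_series <- curves$shank_angle(phi)
  pose <- forward_kinematics(
    hip_sag = truth$sag_angle,
    knee = truth$sag_angle - shank_series,
    ankle = curves$ankle_angle(phi),
    hip_front = truth$front_angle,
    subj = subj, fs = fs_imu)

  if (is.null(lags)) lags <- stats::runif(2, -0.4, 0.4)
  mount <- 121.3
  seeds <- sample.int(.Machine$integer.max - 1, 4)
  imu_shank <- simulate_imu(pose, "shank", mount_angle_deg = mount,
                            noise = noise, seed = seeds[1])
  imu_thigh <- simulate_imu(pose, "thigh", mount_angle_deg = 0,
                            noise = noise, seed = seeds[2])
  imu_shank$t <- imu_shank$t + lags[1]
  imu_thigh$t <- imu_thigh$t + lags[1]

  set.seed(seeds[3])
  t_ins <- sample_times(duration, fs_insole)
  grf <- grf_template(phase_at(t_ins) %% 100, subj$mass_kg, stance)
  # force is zero between the last complete cycle's end and the tail swing
  grf[phase_at(t_ins) > n_hs * 100 + stance * 100] <- 0
  grf <- pmax(grf + stats::rnorm(length(grf), 0, noise$grf %||% 0), 0)
  insole <- insole_stream(t_ins + lags[2], grf, fs = fs_insole)

  set.seed(seeds[4])
  heel_pos <- pose$joints$heel +
    matrix(stats::rnorm(3 * length(t_imu), 0, noise$marker %||% 0),
           ncol = 3)
  heel <- marker_trace(t_imu, heel_pos, fs = fs_imu, name = "heel")

  structure(list(subject = subj, imu_shank = imu_shank,
                 imu_thigh = imu_thigh, insole = insole, heel = heel,
                 truth = truth,
                 meta = list(seed = seed, noise = noise, lags = lags,
                             mount_angle_deg = mount, n_cycles = n_cycles,
                             stance_fraction = stance,
                             cycle_duration_s = T_mean,
                             duration_s = duration)),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> subject %s: %d cycles, %.1f s, stance %.1f%%\n",
              x$subject$id, x$meta$n_cycles, x$meta$duration_s,
              x$meta$stance_fraction * 100))
  invisible(x)
}

#' Generate a synthetic stair-ascent cohort
#'
#' Draws `n_subjects` subjects from the cohort anthropometric distribution
#' and one trial per subject, with per-subject cycle counts ~
#' Normal(4.53, 0.62) (rounded, minimum 3). All randomness derives from the
#' master seed, so the same seed reproduces the cohort exactly.
#'
#' @param n_subjects number of subjects (cohort default 17).
#' @param templates a [default_templates()] object.
#' @param noise noise list as in [default_noise()].
#' @param seed master integer seed.
#' @param n_cycles_mean,n_cycles_sd distribution of cycles per trial.
#' @return A `gait_cohort`: list of [generate_trial()] records.
#' @export
generate_cohort <- function(n_subjects = 17, templates = default_templates(),
                            noise = default_noise(), seed = 1,
                            n_cycles_mean = 4.53, n_cycles_sd = 0.62) {
  stopifnot(n_subjects >= 2)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, n_subjects)
  trial_seeds <- sample.int(.Machine$integer.max - 1, n_subjects)
  n_cyc <- pmax(3L, as.integer(round(stats::rnorm(n_subjects, n_cycles_mean,
                                                  n_cycles_sd))))
  cohort <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    subj <- sample_subject(sub_seeds[i], id = sprintf("S%02d", i))
    cohort[[i]] <- generate_trial(subj, templates, n_cycles = n_cyc[i],
                                  noise = noise, seed = trial_seeds[i])
  }
  structure(cohort, class = "gait_cohort", seed = seed)
}

#' Write / read a cohort as delimited text
#'
#' One directory per subject with the [read_stream()] schemas
#' (`imu_shank.csv`, `imu_thigh.csv`, `insole.csv`, `heel.csv`), the
#' ground-truth curves (`truth.csv`), truth events (`events.csv`), the
#' subject anthropometrics (`subject.json`) and, at the root, a
#' `manifest.json` recording seeds and parameters for exact reproduction.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return `dir` (invisibly) for `write_cohort()`; a `gait_cohort` for
#'   `read_cohort()`.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop("refusing to write into non-empty directory (use force = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort)) {
    tr <- cohort[[i]]
    sd_i <- file.path(dir, sprintf("subject_%02d", i))
    dir.create(sd_i, showWarnings = FALSE)
    write_stream(tr$imu_shank, file.path(sd_i, "imu_shank.csv"))
    write_stream(tr$imu_thigh, file.path(sd_i, "imu_thigh.csv"))
    write_stream(tr$insole, file.path(sd_i, "insole.csv"))
    write_stream(tr$heel, file.path(sd_i, "heel.csv"))
    tdf <- data.frame(t = tr$truth$t, sag_angle = tr$truth$sag_angle,
                      front_angle = tr$truth$front_angle,
                      sag_moment = tr$truth$sag_moment,
                      front_moment = tr$truth$front_moment,
                      phase = tr$truth$phase)
    utils::write.csv(format(tdf, digits = 15, trim = TRUE),
                     file.path(sd_i, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
    edf <- data.frame(hs_time_s = tr$truth$hs_times,
                      to_time_s = c(tr$truth$to_times, NA))
    utils::write.csv(edf, file.path(sd_i, "events.csv"), row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(
      list(id = tr$subject$id, height_m = tr$subject$height_m,
           mass_kg = tr$subject$mass_kg, meta = tr$meta),
      file.path(sd_i, "subject.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(package = "stairgait", n_subjects = length(cohort),
         seed = attr(cohort, "seed")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  dirs <- sort(list.dirs(dir, recursive = FALSE))
  cohort <- vector("list", length(dirs))
  for (i in seq_along(dirs)) {
    sd_i <- dirs[i]
    sj <- jsonlite::read_json(file.path(sd_i, "subject.json"))
    subj <- subject(sj$height_m, sj$mass_kg, id = sj$id)
    tdf <- utils::read.csv(file.path(sd_i, "truth.csv"))
    edf <- utils::read.csv(file.path(sd_i, "events.csv"))
    truth <- list(t = tdf$t, fs = 1 / stats::median(diff(tdf$t)),
                  sag_angle = tdf$sag_angle, front_angle = tdf$front_angle,
                  sag_moment = tdf$sag_moment, front_moment = tdf$front_moment,
                  hs_times = edf$hs_time_s,
                  to_times = edf$to_time_s[!is.na(edf$to_time_s)],
                  stance_fraction = sj$meta$stance_fraction,
                  phase = tdf$phase)
    cohort[[i]] <- structure(
      list(subject = subj,
           imu_shank = read_stream(file.path(sd_i, "imu_shank.csv"), "imu"),
           imu_thigh = read_stream(file.path(sd_i, "imu_thigh.csv"), "imu"),
           insole = read_stream(file.path(sd_i, "insole.csv"), "insole"),
           heel = read_stream(file.path(sd_i, "heel.csv"), "marker"),
           truth = truth,
           meta = lapply(sj$meta, function(x)
             if (is.list(x)) lapply(x, unlist) else unlist(x))),
      class = "trial_record")
  }
  structure(cohort, class = "gait_cohort", seed = man$seed)
}
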