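#' Forward kinematics of the planar lower-limb chain
#'
#' Computes joint centres and segment orientations from hip, knee and ankle
#' angle series for a subject standing on a stair exercise machine, with the
#' hip joint centre fixed at the origin of a pelvis-fixed lab frame
#' (x anterior, y up, z lateral for the instrumented right leg). Sagittal
#' segment angles are measured from the downward vertical (flexion
#' positive); the frontal hip angle (adduction positive) tilts the whole
#' limb chain about the anteroposterior axis through the hip. The talus
#' point -- where the vertical GRF is applied downstream -- is the ankle
#' joint centre. A heel point is carried 30% of foot length posterior to
#' the ankle along the foot axis for virtual marker generation.
#'
#' @param hip_sag,knee,ankle angle series in degrees (equal lengths): hip
#'   flexion, knee flexion, ankle dorsiflexion.
#' @param hip_front frontal hip angle series in degrees (adduction
#'   positive); scalar 0 recycles.
#' @param subj a [subject()].
#' @param fs sampling frequency of the angle series in Hz.
#' @return A `planar_pose`: list with `t`, `fs`, `angles` (data frame of
#'   segment angles in degrees: `thigh`, `shank`, `foot`, `frontal`),
#'   `joints` (list of N x 3 matrices `hip`, `knee`, `ankle`, `toe`,
#'   `heel`), `coms` (N x 3 per segment) and the subject.
#' @export
forward_kinematics <- function(hip_sag, knee, ankle, hip_front = 0, subj, fs) {
  n <- length(hip_sag)
  stopifnot(length(knee) == n, length(ankle) == n)
  if (length(hip_front) == 1) hip_front <- rep(hip_front, n)
  stopifnot(length(hip_front) == n)
  d2r <- pi / 180
  th_t <- hip_sag * d2r
  th_s <- (hip_sag - knee) * d2r
  th_f <- (hip_sag - knee + ankle) * d2r  # foot axis from anterior horizontal
  al <- hip_front * d2r

  Lt <- seg_par(subj, "thigh")$length_m
  Ls <- seg_par(subj, "shank")$length_m
  Lf <- seg_par(subj, "foot")$length_m

  # sagittal-plane chain (x, y), hip at origin
  knee_s <- cbind(Lt * sin(th_t), -Lt * cos(th_t))
  ankle_s <- knee_s + cbind(Ls * sin(th_s), -Ls * cos(th_s))
  toe_s <- ankle_s + cbind(Lf * cos(th_f), Lf * sin(th_f))
  heel_s <- ankle_s - 0.3 * cbind(Lf * cos(th_f), Lf * sin(th_f))

  tilt <- function(p2) cbind(p2[, 1],
                             p2[, 2] * cos(al),
                             p2[, 2] * sin(al))
  joints <- list(hip = matrix(0, n, 3), knee = tilt(knee_s),
                 ankle = tilt(ankle_s), toe = tilt(toe_s),
                 heel = tilt(heel_s))
  com_of <- function(prox, dist, frac) prox + frac * (dist - prox)
  coms <- list(
    thigh = com_of(joints$hip, joints$knee, seg_par(subj, "thigh")$com_frac),
    shank = com_of(joints$knee, joints$ankle, seg_par(subj, "shank")$com_frac),
    foot = com_of(joints$ankle, joints$toe, seg_par(subj, "foot")$com_frac))

  structure(list(t = (seq_len(n) - 1) / fs, fs = fs,
                 angles = data.frame(thigh = hip_sag, shank = hip_sag - knee,
                                     foot = hip_sag - knee + ankle,
                                     frontal = hip_front),
                 joints = joints, coms = coms, subject = subj),
            class = "planar_pose")
}

#' @export
print.planar_pose <- function(x, ...) {
  cat(sprintf("<planar_pose> n=%d fs=%g Hz (%.2f s)\n",
              length(x$t), x$fs, length(x$t) / x$fs))
  invisible(x)
}

#' Virtual IMU simulation from a pose
#'
#' Generates the 13-channel inertial stream a segment-mounted IMU would
#' record: angular velocity of the segment expressed in the sensor frame,
#' proper acceleration of the mount point (linear acceleration minus
#' gravity) in the sensor frame, a constant laboratory magnetic field
#' rotated into the sensor frame, and the sensor orientation quaternion.
#' The sensor frame equals the segment frame rotated about the segment's
#' longitudinal axis by `mount_angle_deg` -- applying
#' [rotate_shank_imu()] with the same angle restores segment-aligned
#' channels. Additive white Gaussian noise is applied per channel group;
#' quaternions are re-normalized after noise.
#'
#' @param pose a [forward_kinematics()] result.
#' @param segment `"shank"` or `"thigh"`.
#' @param mount_angle_deg mounting rotation about the longitudinal axis
#'   (anteromedial shank mounting corresponds to the cohort mean 121.3).
#' @param noise named list of channel noise SDs: `gyro` (rad/s), `acc`
#'   (m/s^2), `mag` (a.u.), `quat` (unitless).
#' @param seed integer seed for the noise draw.
#' @return An [imu_stream()] at the pose sampling rate.
#' @export
simulate_imu <- function(pose, segment = c("shank", "thigh"),
                         mount_angle_deg = 0,
                         noise = list(gyro = 0, acc = 0, mag = 0, quat = 0),
                         seed = NULL) {
  segment <- match.arg(segment)
  stopifnot(inherits(pose, "planar_pose"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(pose$t)
  fs <- pose$fs
  d2r <- pi / 180
  th <- pose$angles[[if (segment == "shank") "shank" else "thigh"]] * d2r
  al <- pose$angles$frontal * d2r
  thd <- central_diff(th, fs)
  ald <- central_diff(al, fs)

  prox <- if (segment == "shank") pose$joints$knee else pose$joints$hip
  dist <- if (segment == "shank") pose$joints$ankle else pose$joints$knee
  pm <- prox + 0.5 * (dist - prox)
  am <- apply(pm, 2, function(col) central_diff(central_diff(col, fs), fs))

  Rm <- rot_long(mount_angle_deg * d2r)
  g_vec <- c(0, -9.81, 0)
  B_lab <- c(25, -43.3, 0)  # Earth-like field with downward dip, a.u.

  gyro <- acc <- mag <- matrix(0, n, 3)
  quat <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    Rx_i <- rot_x(al[i])
    R_seg <- Rx_i %*% rot_z(th[i])
    R_sens <- R_seg %*% Rm
    w_lab <- c(ald[i], 0, 0) + Rx_i %*% c(0, 0, thd[i])
    gyro[i, ] <- crossprod(R_sens, w_lab)
    acc[i, ] <- crossprod(R_sens, am[i, ] - g_vec)
    mag[i, ] <- crossprod(R_sens, B_lab)
    q <- quat_from_matrix(R_sens)
    if (i > 1 && sum(q * quat[i - 1, ]) < 0) q <- -q
    quat[i, ] <- q
  }
  gyro <- gyro + stats::rnorm(3 * n, 0, noise$gyro %||% 0)
  acc <- acc + stats::rnorm(3 * n, 0, noise$acc %||% 0)
  mag <- mag + stats::rnorm(3 * n, 0, noise$mag %||% 0)
  quat <- quat + stats::rnorm(4 * n, 0, noise$quat %||% 0)
  quat <- quat / sqrt(rowSums(quat^2))
  imu_stream(pose$t, acc = acc, gyro = gyro, mag = mag, quat = quat,
             fs = fs, segment = segment)
}

#' Hip inverse dynamics with the vertical GRF applied at the talus
#'
#' Bottom-up Newton-Euler over foot, shank and thigh. Sagittal plane:
#' full dynamics (segment weights, COM accelerations, angular
#' accelerations) with the measured vertical GRF as the only external load,
#' applied at the talus point (the ankle joint centre), optionally shifted
#' by `cop_offset_m`. Frontal plane: quasi-static balance about the
#' anteroposterior axis through the hip (frontal inertial terms are small
#' during stair ascent and are neglected). During swing the force is ~0 N
#' and the moments are driven purely by segment inertial and gravitational
#' terms.
#'
#' Sign conventions match the reported curves: sagittal moments are flexion
#' positive / extension negative; frontal moments are adduction positive /
#' abduction negative (so the stance abductor moment is negative). Both are
#' internal net joint moments normalized by body mass (Nm/kg).
#'
#' @param pose a [forward_kinematics()] result.
#' @param grf_v vertical GRF series in newtons, sampled on the pose grid.
#' @param subj a [subject()]; defaults to the pose's subject.
#' @param cop_offset_m length-3 offset (m, lab frame) added to the talus
#'   load point, e.g. `c(0.01, 0, 0)` for a 1 cm anterior shift.
#' @return List with numeric vectors `sagittal` and `frontal` (Nm/kg).
#' @export
inverse_dynamics_hip <- function(pose, grf_v, subj = pose$subject,
                                 cop_offset_m = c(0, 0, 0)) {
  stopifnot(inherits(pose, "planar_pose"))
  n <- length(pose$t)
  stopifnot(length(grf_v) == n)
  if (subj$mass_kg <= 0) stop("subject mass must be positive")
  fs <- pose$fs
  d2r <- pi / 180
  g <- c(0, -9.81)
  load_pt <- pose$joints$ankle + matrix(cop_offset_m, n, 3, byrow = TRUE)

  seg_names <- c("foot", "shank", "thigh")
  prox_j <- list(foot = pose$joints$ankle, shank = pose$joints$knee,
                 thigh = pose$joints$hip)
  dist_j <- list(foot = pose$joints$toe, shank = pose$joints$ankle,
                 thigh = pose$joints$knee)
  ang <- list(foot = pose$angles$foot, shank = pose$angles$shank,
              thigh = pose$angles$thigh)

  cross2 <- function(r, f) r[, 1] * f[, 2] - r[, 2] * f[, 1]

  F_dist <- matrix(0, n, 2)   # force applied on segment at its distal joint
  M_dist <- numeric(n)        # moment applied on segment at its distal joint
  F_ext <- cbind(rep(0, n), grf_v)
  for (s in seg_names) {
    sp <- seg_par(subj, s)
    m <- sp$mass_kg
    I <- m * (sp$rg_frac * sp$length_m)^2
    com <- pose$coms[[s]][, 1:2, drop = FALSE]
    a_com <- apply(com, 2, function(col) central_diff(central_diff(col, fs), fs))
    th_dd <- central_diff(central_diff(ang[[s]] * d2r, fs), fs)
    ext_F <- if (s == "foot") F_ext else matrix(0, n, 2)
    ext_r <- if (s == "foot") load_pt[, 1:2, drop = FALSE] - com else NULL
    F_prox <- a_com * m - matrix(m * g, n, 2, byrow = TRUE) - F_dist - ext_F
    M_prox <- I * th_dd - M_dist -
      cross2(prox_j[[s]][, 1:2, drop = FALSE] - com, F_prox) -
      cross2(dist_j[[s]][, 1:2, drop = FALSE] - com, F_dist)
    if (s == "foot") M_prox <- M_prox - cross2(ext_r, ext_F)
    # reaction on the next (proximal) segment
    F_dist <- -F_prox
    M_dist <- -M_prox
  }
  sagittal <- -M_dist / subj$mass_kg  # = M_prox of thigh; +z is flexion

  ## frontal plane: quasi-static balance of the whole limb about the hip AP
  ## axis; (r x F)_x = r_y F_z - r_z F_y, and all forces are vertical.
  M_ext_x <- -(load_pt[, 3] - 0) * grf_v
  for (s in seg_names) {
    sp <- seg_par(subj, s)
    M_ext_x <- M_ext_x - pose$coms[[s]][, 3] * (-sp$mass_kg * 9.81)
  }
  M_int_x <- -M_ext_x
  # +x rotation carries the limb medially (adduction), so M_int_x is already
  # adduction positive; the stance abductor moment comes out negative.
  frontal <- M_int_x / subj$mass_kg
  list(sagittal = sagittal, frontal = frontal)
}
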