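test_that("forward kinematics places joints by trigonometry", {
  subj <- fx_subject()
  Lt <- subj$segments$length_m[1]
  Ls <- subj$segments$length_m[2]
  n <- 5
  # reference posture: stacked vertical segments, talus below hip
  p0 <- forward_kinematics(rep(0, n), rep(0, n), rep(0, n), 0, subj, 128)
  expect_equal(p0$joints$ankle[1, ], c(0, -(Lt + Ls), 0), tolerance = 1e-12)
  # hip flexion 90, knee 0: thigh horizontal
  p90 <- forward_kinematics(rep(90, n), rep(0, n), rep(0, n), 0, subj, 128)
  expect_equal(p90$joints$knee[1, ], c(Lt, 0, 0), tolerance = 1e-12)
  # rigid segments under random angle series
  set.seed(8)
  pr <- forward_kinematics(runif(50, -20, 90), runif(50, 0, 100),
                           runif(50, -20, 20), runif(50, -10, 10), subj, 128)
  thl <- sqrt(rowSums((pr$joints$knee - pr$joints$hip)^2))
  shl <- sqrt(rowSums((pr$joints$ankle - pr$joints$knee)^2))
  expect_true(all(abs(thl - Lt) < 1e-9))
  expect_true(all(abs(shl - Ls) < 1e-9))
})

test_that("virtual IMU reproduces statics, rates and seeds", {
  subj <- fx_subject()
  n <- 256
  static <- forward_kinematics(rep(20, n), rep(30, n), rep(0, n), 5, subj, 128)
  s <- simulate_imu(static, "shank", mount_angle_deg = 121.3)
  expect_true(all(abs(s$gyro) < 1e-9))
  expect_equal(sqrt(rowSums(s$acc^2)), rep(9.81, n), tolerance = 1e-6)
  # constant angular velocity about the mediolateral axis
  omega_deg <- 40  # deg/s
  ramp <- forward_kinematics(omega_deg * (0:(n - 1)) / 128, rep(0, n),
                             rep(0, n), 0, subj, 128)
  th <- simulate_imu(ramp, "thigh")
  expect_equal(th$gyro[, 3], rep(omega_deg * pi / 180, n), tolerance = 1e-9)
  # reproducibility contract
  nz <- list(gyro = 0.05, acc = 0.3, mag = 0.1, quat = 0.002)
  a <- simulate_imu(static, "shank", 121.3, noise = nz, seed = 11)
  b <- simulate_imu(static, "shank", 121.3, noise = nz, seed = 11)
  c <- simulate_imu(static, "shank", 121.3, noise = nz, seed = 12)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$acc, c$acc)))
})

test_that("mount offset and re-alignment are inverse operations", {
  trial <- fx_trial_clean()
  pose <- forward_kinematics(trial$truth$sag_angle,
                             trial$truth$sag_angle -
                               template_curve(default_templates(),
                                              "shank_angle", trial$truth$phase),
                             template_curve(default_templates(), "ankle_angle",
                                            trial$truth$phase),
                             trial$truth$front_angle, trial$subject, 128)
  mounted <- simulate_imu(pose, "shank", mount_angle_deg = 121.3)
  aligned <- rotate_shank_imu(mounted, 121.3)
  reference <- simulate_imu(pose, "shank", mount_angle_deg = 0)
  for (nm in c("acc", "gyro", "mag"))
    expect_equal(aligned[[nm]], reference[[nm]], tolerance = 1e-9)
  expect_lt(max(abs(abs(rowSums(aligned$quat * reference$quat)) - 1)), 1e-9)
})

test_that("hip inverse dynamics matches an independent static free body", {
  subj <- fx_subject()
  n <- 64
  pose <- forward_kinematics(rep(25, n), rep(35, n), rep(5, n), 8, subj, 128)
  G <- subj$mass_kg * 9.81 * 0.9
  id <- inverse_dynamics_hip(pose, rep(G, n), subj)
  # independent static free-body computation (sum of external moments about
  # the hip, gravity + GRF at the talus, internal moment balances them)
  ext_z <- pose$joints$ankle[1, 1] * G
  ext_x <- -pose$joints$ankle[1, 3] * G
  for (seg in c("thigh", "shank", "foot")) {
    m <- subj$segments$mass_kg[match(seg, subj$segments$segment)]
    ext_z <- ext_z + pose$coms[[seg]][1, 1] * (-m * 9.81)
    ext_x <- ext_x - pose$coms[[seg]][1, 3] * (-m * 9.81)
  }
  expect_equal(id$sagittal[n / 2], -ext_z / subj$mass_kg, tolerance = 1e-6)
  expect_equal(id$frontal[n / 2], -ext_x / subj$mass_kg, tolerance = 1e-6)
  # zero GRF: gravitational terms only
  id0 <- inverse_dynamics_hip(pose, rep(0, n), subj)
  ext_z0 <- ext_z - pose$joints$ankle[1, 1] * G
  expect_equal(id0$sagittal[n / 2], -ext_z0 / subj$mass_kg, tolerance = 1e-6)
})

test_that("moments are mass-normalized and respond to CoP shifts", {
  tr <- fx_trial_clean()
  tpl <- default_templates()
  phase <- tr$truth$phase
  kin <- list(hip = tr$truth$sag_angle,
              knee = tr$truth$sag_angle - template_curve(tpl, "shank_angle", phase),
              ankle = template_curve(tpl, "ankle_angle", phase),
              front = tr$truth$front_angle)
  s1 <- subject(1.74, 70, "a")
  s2 <- subject(1.74, 140, "b")
  grf_bw <- grf_template(phase %% 100, 1, 0.67)  # per unit mass
  p1 <- forward_kinematics(kin$hip, kin$knee, kin$ankle, kin$front, s1, 128)
  p2 <- forward_kinematics(kin$hip, kin$knee, kin$ankle, kin$front, s2, 128)
  id1 <- inverse_dynamics_hip(p1, grf_bw * 70, s1)
  id2 <- inverse_dynamics_hip(p2, grf_bw * 140, s2)
  expect_equal(id1$sagittal, id2$sagittal, tolerance = 1e-9)
  expect_equal(id1$frontal, id2$frontal, tolerance = 1e-9)
  # anterior CoP shift increases the peak extension-phase moment magnitude
  stance <- phase %% 100 < 67
  base <- inverse_dynamics_hip(p1, grf_bw * 70, s1)
  shft <- inverse_dynamics_hip(p1, grf_bw * 70, s1, cop_offset_m = c(0.01, 0, 0))
  trim <- seq(65, length(phase) - 65)  # avoid differentiation edge effects
  expect_gt(max(-shft$sagittal[trim][stance[trim]]),
            max(-base$sagittal[trim][stance[trim]]))
  bad <- s1
  bad$mass_kg <- -1
  expect_error(inverse_dynamics_hip(p1, grf_bw * 70, bad), "positive")
})
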