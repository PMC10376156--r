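test_that("default templates reproduce the calibration landmarks", {
  tpl <- default_templates()
  p <- seq(0, 100, by = 0.01)
  sag <- template_curve(tpl, "sag_angle", p)
  expect_equal(diff(range(sag)), 55.6, tolerance = 1e-9)
  expect_equal(template_curve(tpl, "sag_angle", 0), 58.0, tolerance = 1e-9)
  expect_equal(diff(range(template_curve(tpl, "front_angle", p))), 17.4,
               tolerance = 1e-9)
  sm <- template_curve(tpl, "sag_moment", p)
  expect_equal(max(sm), 1.0, tolerance = 1e-9)
  expect_equal(p[which.max(sm)], 50, tolerance = 3)    # flexion peak ~50%
  expect_equal(p[which.min(sm)], 20, tolerance = 3)    # extension peak ~20%
  fm <- template_curve(tpl, "front_moment", p)
  expect_equal(min(fm), -1.6, tolerance = 1e-9)
  expect_equal(fm[p == 30], -1.3, tolerance = 0.05)
  # double abduction bump in stance, first peak larger than second
  d <- diff(fm)
  pk <- which(d[-1] > 0 & d[-length(d)] < 0) + 1
  pk <- pk[fm[pk] < -0.5]
  expect_length(pk, 2)
  expect_lt(fm[pk[1]], fm[pk[2]])
  expect_lt(p[pk[1]], p[pk[2]])
  # periodicity of every curve
  for (m in c("sag_angle", "front_angle", "sag_moment", "front_moment",
              "shank_angle", "knee_angle", "ankle_angle"))
    expect_equal(template_curve(tpl, m, 0), template_curve(tpl, m, 100),
                 tolerance = 1e-9)
  # knee fixture stays physiological (no hyperextension, moderate flexion)
  kn <- template_curve(tpl, "knee_angle", p)
  expect_gt(min(kn), 0)
  expect_lt(max(kn), 120)
})

test_that("subject sampling reproduces the cohort distribution", {
  s1 <- sample_subject(42)
  s2 <- sample_subject(42)
  expect_identical(s1[c("height_m", "mass_kg")], s2[c("height_m", "mass_kg")])
  set.seed(1)
  hs <- replicate(10000, {
    h <- stats::rnorm(1, 1.74, 0.08)
    while (h <= 0.5) h <- stats::rnorm(1, 1.74, 0.08)
    h
  })
  expect_equal(mean(hs), 1.74, tolerance = 0.01)
  masses <- vapply(1:200, function(i) sample_subject(i)$mass_kg, 0)
  expect_true(all(masses > 0))
})

test_that("the GRF template is zero in swing and scales with mass", {
  expect_equal(grf_template(80, 81.6, 0.67), 0)
  expect_equal(grf_template(c(70, 90, 99), 81.6, 0.67), c(0, 0, 0))
  p <- seq(0, 100, by = 0.01)
  g1 <- grf_template(p, 60, 0.67)
  g2 <- grf_template(p, 120, 0.67)
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
  # rises through 20 N exactly once per cycle
  y <- grf_template(p, 81.6, 0.67)
  expect_equal(sum(y[-1] > 20 & y[-length(y)] <= 20), 1)
})

test_that("cohort generation is deterministic and degenerates cleanly", {
  c1 <- generate_cohort(3, seed = 9, noise = zero_noise())
  c2 <- generate_cohort(3, seed = 9, noise = zero_noise())
  expect_identical(c1, c2)
  c3 <- generate_cohort(3, seed = 10, noise = zero_noise())
  expect_false(identical(c1, c3))
  # zero jitter + zero noise: truth equals the default template curves
  tpl0 <- default_templates(subject_scale_sd = 0, angle_offset_sd_deg = 0,
                            moment_offset_sd = 0, cycle_duration_sd_s = 0,
                            stance_fraction_sd = 0, cycle_jitter_sd = 0)
  tr <- generate_trial(subject(1.74, 81.6), tpl0, n_cycles = 3,
                       noise = zero_noise(), seed = 4, lags = c(0, 0))
  expect_equal(tr$truth$sag_angle,
               template_curve(tpl0, "sag_angle", tr$truth$phase),
               tolerance = 1e-3)
  expect_equal(tr$truth$front_moment,
               template_curve(tpl0, "front_moment", tr$truth$phase),
               tolerance = 1e-9)
  expect_equal(tr$meta$stance_fraction, 0.67)
})

test_that("cohort-level sagittal ROM stays near the template under jitter", {
  cohort <- generate_cohort(17, seed = 1)
  roms <- vapply(cohort, function(tr) diff(range(tr$truth$sag_angle)), 0)
  expect_equal(mean(roms), 55.6, tolerance = 2)
  # truth events line up with the insole force threshold crossings
  for (tr in cohort[1:3]) {
    ev <- detect_events_insole(
      insole_stream(tr$insole$t - tr$meta$lags[2], tr$insole$grf_v,
                    tr$insole$fs))
    err <- fx_event_err(ev$hs_times, tr$truth$hs_times, tr$insole$fs)
    expect_lt(max(abs(err)), 2.5)  # default 5 N noise on a steep onset
  }
})

test_that("cohorts round-trip through the delimited-text layout", {
  d <- withr::local_tempdir()
  cohort <- generate_cohort(2, seed = 21)
  write_cohort(cohort, d, force = TRUE)
  expect_error(write_cohort(cohort, d), "non-empty")
  back <- read_cohort(d)
  expect_length(back, 2)
  expect_equal(back[[1]]$subject$mass_kg, cohort[[1]]$subject$mass_kg,
               tolerance = 1e-9)
  expect_equal(back[[1]]$imu_shank$gyro, cohort[[1]]$imu_shank$gyro,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back[[2]]$truth$sag_moment, cohort[[2]]$truth$sag_moment,
               tolerance = 1e-9)
  expect_equal(back[[1]]$truth$hs_times, cohort[[1]]$truth$hs_times,
               tolerance = 1e-9)
})
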