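test_that("insole detector handles pulses, silence and alternation", {
  fs <- 100
  t <- sample_times(3, fs)
  pulse <- ifelse(t >= 1 & t < 2, 600, 0)
  ev <- detect_events_insole(insole_stream(t, pulse, fs))
  expect_length(ev$hs_times, 1)
  expect_length(ev$to_times, 1)
  expect_equal(ev$hs_times, 1, tolerance = 1.5 / fs)
  expect_equal(ev$to_times, 2, tolerance = 1.5 / fs)
  expect_equal(ev$n_cycles, 0)  # a single pulse is not a complete cycle
  ev0 <- detect_events_insole(insole_stream(t, rep(0, length(t)), fs))
  expect_equal(ev0$n_cycles, 0)
  expect_length(ev0$hs_times, 0)
})

test_that("insole events recover the stance fraction of a synthetic train", {
  fs <- 128
  cyc <- 10 / 4.53
  t <- sample_times(5 * cyc, fs)
  grf <- grf_template((t / cyc * 100) %% 100, mass_kg = 81.6,
                      stance_fraction = 0.67)
  ev <- detect_events_insole(insole_stream(t, grf, fs), threshold = 20)
  expect_equal(ev$n_cycles, 4)
  # within one sample period, expressed in stance percent
  expect_equal(mean(ev$stance_fraction) * 100, 67.0,
               tolerance = 100 / (fs * cyc))
  # event alternation: hs < to < next hs
  for (i in seq_len(ev$n_cycles)) {
    expect_gt(ev$to_times[i], ev$hs_times[i])
    expect_lt(ev$to_times[i], ev$hs_times[i + 1])
  }
})

test_that("optical detector finds the analytic crossing of a single stride", {
  fs <- 128
  t <- sample_times(3, fs)
  # one swing: AP velocity A*sin(2*pi*(t-1)) on [1, 1.5], zero elsewhere;
  # downward zero crossing at t = 1.5
  A <- 1.2
  v <- ifelse(t >= 1 & t <= 1.5, A * sin(2 * pi * (t - 1)), 0)
  x <- cumsum(v) / fs
  hs <- detect_hs_mocap(marker_trace(t, cbind(x, 0, 0), fs))
  expect_length(hs, 1)
  expect_equal(hs, 1.5, tolerance = 1.5 / fs)
  # stationary marker: no swing, no events
  expect_length(detect_hs_mocap(marker_trace(t, matrix(0, length(t), 3), fs)),
                0)
})

test_that("IMU detector needs two stance minima and ignores flat signals", {
  fs <- 128
  t <- sample_times(4, fs)
  s <- fx_flat_imu(length(t))
  expect_length(detect_hs_imu(s), 0)  # constant signal
  # pure sine has one minimum between successive peaks: regions are skipped
  s$gyro[, 3] <- sin(2 * pi * t)
  expect_message(out <- detect_hs_imu(s), "skipped")
  expect_length(out, 0)
  # the minima themselves sit at the analytic positions
  mins <- stairgait:::local_extrema(s$gyro[, 3], "min")
  expect_equal(t[mins], c(0.75, 1.75, 2.75, 3.75), tolerance = 1.5 / fs)
})

test_that("all three detectors recover generator heel strikes", {
  for (trial in list(fx_trial_clean(), fx_trial_noisy())) {
    fs <- 128
    prep <- fx_prepared(trial)
    hs_true <- trial$truth$hs_times
    hs_m <- detect_hs_mocap(prep$heel)
    expect_gte(length(hs_m), trial$meta$n_cycles)
    err_m <- fx_event_err(hs_m, hs_true, fs)
    expect_lt(max(abs(err_m)), 2)
    # the 10 Hz zero-phase filter smears the loading edge slightly forward,
    # so the insole is judged at its own 100 Hz sample period
    ev <- detect_events_insole(prep$insole)
    expect_gte(ev$n_cycles, trial$meta$n_cycles - 1)
    err_i <- fx_event_err(ev$hs_times - trial$meta$lags[2], hs_true,
                          trial$insole$fs)
    expect_lt(max(abs(err_i)), 2)
    hs_g <- detect_hs_imu(prep$shank) - trial$meta$lags[1]
    expect_gte(length(hs_g), trial$meta$n_cycles - 1)
    err_g <- fx_event_err(hs_g, hs_true, fs)
    expect_lt(max(abs(err_g)), 2)
  }
  # the optical detector is within one sample on noise-free data
  prep <- fx_prepared(fx_trial_clean())
  err <- fx_event_err(detect_hs_mocap(prep$heel), fx_trial_clean()$truth$hs_times, 128)
  expect_lt(max(abs(err)), 1)
})

test_that("synchronization aligns first heel strikes and crops overlap", {
  trial <- fx_trial_clean()   # generated with lags +0.35 (IMU), -0.20 (insole)
  prep <- fx_prepared(trial)
  hs_m <- detect_hs_mocap(prep$heel)[1]
  ev <- detect_events_insole(prep$insole)
  hs_g <- detect_hs_imu(prep$shank)[1]
  sync <- synchronize(hs_m, prep$shank, prep$insole, hs_g, ev$hs_times[1],
                      extra_imu = trial$imu_thigh)
  hs_g2 <- detect_hs_imu(sync$imu)[1]
  ev2 <- detect_events_insole(sync$insole)
  expect_lt(abs(hs_g2 - hs_m), 1 / (2 * 128) + 1e-9)
  expect_lt(abs(ev2$hs_times[1] - hs_m), 1 / (2 * 100) + 1e-9)
  # zero lags on co-spanning streams: identity
  s1 <- fx_flat_imu(256)
  ins_t <- sample_times(2, 128)
  ins1 <- insole_stream(ins_t, 100 + 50 * sin(ins_t), 128)
  same <- synchronize(0.5, s1, ins1, 0.5, 0.5)
  expect_equal(same$imu$t, s1$t)
  expect_equal(same$insole$grf_v, ins1$grf_v)
  # a lag longer than the stream kills the overlap
  expect_error(synchronize(1000, prep$shank, prep$insole, 1, 1000 + 100),
               "overlap")
})

test_that("gait-percent normalization is exact on constants and clocks", {
  fs <- 128
  t <- sample_times(3.2, fs)
  # heel strikes on exact sample instants so the sawtooth clock signal below
  # interpolates cleanly at cycle starts
  ev <- gait_events(hs_times = (13 + (0:3) * 128) / fs,
                    to_times = (13 + (0:2) * 128) / fs + 0.7)
  cm <- normalize_to_gait_percent(rep(4.2, length(t)), fs, ev)
  expect_equal(dim(cm), c(3, 101))
  expect_true(all(abs(cm - 4.2) < 1e-12))
  # a signal equal to elapsed time within the cycle -> 0 -> duration ramps
  # (the value exactly at 100% belongs to the next cycle's sawtooth, so the
  # ramp is checked at interior grid points)
  idx <- findInterval(t, ev$hs_times)
  elapsed <- ifelse(idx >= 1, t - ev$hs_times[pmax(idx, 1)], 0)
  cm2 <- normalize_to_gait_percent(elapsed, fs, ev)
  for (i in 1:3) {
    expect_equal(cm2[i, 1], 0, tolerance = 2 / fs)
    expect_equal(cm2[i, 51], 0.5, tolerance = 2 / fs)
    expect_equal(cm2[i, 96], 0.95, tolerance = 2 / fs)
  }
  expect_error(normalize_to_gait_percent(rep(1, 10), fs,
                                         gait_events(1, numeric(0))),
               "no complete gait cycle")
})

test_that("ensemble averages match hand computations and balance", {
  m <- rbind(rep(1, 101), rep(1, 101))
  ea <- ensemble_average(m)
  expect_equal(ea$sd, rep(0, 101))
  two <- rbind(rep(0, 5), rep(2, 5))
  ea2 <- ensemble_average(two)
  expect_equal(ea2$mean, rep(1, 5))
  expect_equal(ea2$sd, rep(sqrt(2), 5))
  # balanced counts: grand mean equals mean of subject means
  set.seed(3)
  s1 <- matrix(rnorm(3 * 7), 3)
  s2 <- matrix(rnorm(3 * 7), 3)
  grand <- ensemble_average(rbind(s1, s2))$mean
  subj <- colMeans(rbind(ensemble_average(s1)$mean, ensemble_average(s2)$mean))
  expect_equal(grand, subj, tolerance = 1e-12)
})
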