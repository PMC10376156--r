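# Shared fixtures, generated once per test run and memoized.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

fx_subject <- function() fx_memo("subject", function() subject(1.74, 81.6, "FX"))

# zero-sensor-noise trial with default subject jitter
fx_trial_clean <- function() fx_memo("trial_clean", function()
  generate_trial(fx_subject(), default_templates(), n_cycles = 5,
                 noise = zero_noise(), seed = 7, lags = c(0.35, -0.20)))

# default sensor noise
fx_trial_noisy <- function() fx_memo("trial_noisy", function()
  generate_trial(fx_subject(), default_templates(), n_cycles = 5,
                 noise = default_noise(), seed = 7, lags = c(0.35, -0.20)))

# small zero-noise cohort for pipeline-level checks
fx_cohort_clean <- function() fx_memo("cohort_clean", function()
  generate_cohort(n_subjects = 6, noise = zero_noise(), seed = 5))

# degenerate cohort: no sensor noise, no subject jitter (subjects differ in
# anthropometrics only) -- the memorization setting for closure checks
fx_cohort_degenerate <- function() fx_memo("cohort_degenerate", function()
  generate_cohort(n_subjects = 8, noise = zero_noise(), seed = 5,
                  templates = default_templates(
                    subject_scale_sd = 0, angle_offset_sd_deg = 0,
                    moment_offset_sd = 0, cycle_duration_sd_s = 0,
                    stance_fraction_sd = 0, cycle_jitter_sd = 0)))

# minimal valid IMU stream
fx_flat_imu <- function(n = 32, fs = 128, segment = "shank") {
  imu_stream(t = (seq_len(n) - 1) / fs,
             acc = matrix(rep(c(0, 9.81, 0), each = n), n, 3),
             gyro = matrix(0, n, 3), mag = matrix(1, n, 3),
             quat = cbind(rep(1, n), 0, 0, 0), fs = fs, segment = segment)
}

# filter a trial's streams the way the pipeline does, for detector tests
fx_prepared <- function(trial) {
  heel <- trial$heel
  heel$pos <- apply(heel$pos, 2, lowpass, fs = heel$fs, spec = filter_spec(6))
  ins <- trial$insole
  ins$grf_v <- pmax(lowpass(ins$grf_v, ins$fs, filter_spec(10)), 0)
  shank <- rotate_shank_imu(trial$imu_shank, 121.3)
  shank$gyro[, 3] <- lowpass(shank$gyro[, 3], shank$fs, filter_spec(2.3))
  list(heel = heel, insole = ins, shank = shank)
}

# timing error (samples) of each detected event against its nearest truth
# event; trailing truth events may legitimately go undetected (incomplete
# final cycles are dropped), so the match runs detected -> truth
fx_event_err <- function(detected, truth, fs) {
  vapply(detected, function(h) (h - truth[which.min(abs(truth - h))]) * fs, 0)
}
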