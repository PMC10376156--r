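test_that("streams validate their invariants", {
  s <- fx_flat_imu(16)
  expect_s3_class(s, "imu_stream")
  bad_q <- cbind(rep(2, 16), 0, 0, 0)
  expect_error(imu_stream(s$t, s$acc, s$gyro, s$mag, bad_q, 128, "shank"),
               "unit norm")
  tj <- s$t; tj[5] <- tj[5] + 0.3 / 128
  expect_error(imu_stream(tj, s$acc, s$gyro, s$mag, s$quat, 128, "shank"),
               "jitter")
  expect_error(insole_stream(1:3 / 100, c(0, 1), 100), "same length")
  # negative forces are clamped, not rejected
  expect_equal(insole_stream(0:2 / 100, c(-5, 10, 20), 100)$grf_v[1], 0)
})

test_that("stream files round-trip losslessly and enforce their schema", {
  tr <- fx_trial_clean()
  d <- withr::local_tempdir()
  for (obj in list(tr$imu_shank, tr$insole, tr$heel)) {
    p <- file.path(d, "s.csv")
    write_stream(obj, p)
    back <- read_stream(p, schema = switch(class(obj),
                                           imu_stream = "imu",
                                           insole_stream = "insole",
                                           marker_trace = "marker"))
    for (nm in setdiff(names(obj), c("t"))) {
      if (is.numeric(obj[[nm]]))
        expect_equal(back[[nm]], obj[[nm]], tolerance = 1e-9,
                     ignore_attr = TRUE)
    }
    expect_equal(back$t, obj$t, tolerance = 1e-9)
  }
  # missing column -> schema error
  p2 <- file.path(d, "imu.csv")
  write_stream(tr$imu_shank, p2)
  df <- utils::read.csv(p2, comment.char = "#")
  df$quat_w <- NULL
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_stream(p2, "imu", segment = "shank"), "quat_w")
})

test_that("short sensor dropouts are interpolated, long ones rejected", {
  tr <- fx_trial_clean()
  d <- withr::local_tempdir()
  p <- file.path(d, "ins.csv")
  write_stream(tr$insole, p)
  df <- utils::read.csv(p, comment.char = "#")
  df$grf_v[50:54] <- NA               # 0.05 s at 100 Hz: interpolated
  utils::write.csv(df, p, row.names = FALSE)
  expect_silent(s <- read_stream(p, "insole", fs = 100))
  expect_false(anyNA(s$grf_v))
  df$grf_v[100:115] <- NA             # 0.16 s: too long
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_stream(p, "insole", fs = 100), "dropout")
})

test_that("lowpass has the designed magnitude response and unity DC gain", {
  t <- sample_times(4, 128)
  spec <- filter_spec(10)
  expect_lt(max(abs(lowpass(rep(3.7, 512), 128, spec) - 3.7)), 1e-9)
  ramp <- seq(0, 1, length.out = 512)
  expect_lt(max(abs(lowpass(ramp, 128, spec) - ramp)), 1e-9)
  hi <- sin(2 * pi * 50 * t)
  expect_lt(max(abs(lowpass(hi, 128, spec)[100:400])), 0.01)
  lo <- sin(2 * pi * 1 * t)
  expect_equal(max(abs(lowpass(lo, 128, spec)[100:400])), 1, tolerance = 0.02)
  expect_error(lowpass(lo, 128, filter_spec(70)), "Nyquist")
  expect_error(lowpass(lo[1:10], 128, spec), "too short")
})

test_that("resample_to follows the length formula and is exact on lines", {
  # N samples at 100 Hz span (N-1)/100 s; the 128 Hz grid over that span has
  # floor((N-1) * 128/100) + 1 points
  expect_length(resample_to(rep(1, 100), 100, 128), 127)
  expect_length(resample_to(rep(1, 101), 100, 128), 129)  # a full 1 s span
  expect_true(all(resample_to(rep(2.5, 100), 100, 128) == 2.5))
  ramp <- seq(0, 5, length.out = 100)
  out <- resample_to(ramp, 100, 128)
  t_out <- (seq_along(out) - 1) / 128
  expect_equal(out, 5 * t_out / 0.99, tolerance = 1e-12)  # still a line
  expect_identical(resample_to(ramp, 100, 100), ramp)
  expect_error(resample_to(1, 100, 128), "at least 2")
})

test_that("shank re-alignment rotates vectors and preserves norms", {
  s <- fx_flat_imu(8)
  s$acc <- matrix(rep(c(1, 0, 0), each = 8), 8, 3)  # anterior unit vector
  r0 <- rotate_shank_imu(s, 0)
  expect_equal(r0$acc, s$acc, tolerance = 1e-12)
  expect_equal(r0$quat, s$quat, tolerance = 1e-12)
  a <- 121.3
  r <- rotate_shank_imu(s, a)
  expect_equal(r$acc[1, ], c(cos(a * pi / 180), 0, sin(a * pi / 180)),
               tolerance = 1e-12)
  # isometry on a real gyro signal
  tr <- fx_trial_noisy()
  rr <- rotate_shank_imu(tr$imu_shank, a)
  expect_equal(sqrt(rowSums(rr$gyro^2)), sqrt(rowSums(tr$imu_shank$gyro^2)),
               tolerance = 1e-12)
  # inverse rotation recovers the stream
  back <- rotate_shank_imu(rr, -a)
  expect_equal(back$gyro, tr$imu_shank$gyro, tolerance = 1e-9)
  # quaternions recover up to the q ~ -q ambiguity
  expect_lt(max(abs(abs(rowSums(back$quat * tr$imu_shank$quat)) - 1)), 1e-9)
  expect_error(rotate_shank_imu(tr$imu_thigh, a), "shank")
})
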