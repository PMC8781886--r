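test_that("reference resampling z-scores then interpolates linearly", {
  # 60 Hz unit ramp sampled at 30 Hz frame times hits every second sample
  ramp <- pulse_trace(0:59, rate = 60)
  ft <- seq(0, 59 / 60, by = 1 / 30)
  out <- resample_reference(ramp, ft)
  z <- (0:59 - mean(0:59)) / sd(0:59)
  expect_equal(out$samples, z[seq(1, 60, by = 2)], tolerance = 1e-12)
  expect_equal(out$rate, 30)

  expect_error(resample_reference(ramp, c(0, 2)), "outside")
  expect_warning(out0 <- resample_reference(pulse_trace(rep(3, 60), 60), ft),
                 "constant")
  expect_equal(out0$samples, rep(0, length(ft)))
})

test_that("resampling a sine preserves its frequency content", {
  tr <- sine_trace(1.2, rate = 60, duration = 20)
  ft <- seq(0, 20 - 1 / 30, by = 1 / 30)
  out <- resample_reference(tr, ft)
  hr <- estimate_hr_window(pulse_trace(out$samples[1:300], 30))
  expect_equal(hr, 72, tolerance = 0.5)
})

test_that("band-pass rejects DC, keeps the passband, kills the stopband", {
  dc <- pulse_trace(rep(5, 300), rate = 30)
  expect_lt(max(abs(bandpass(dc)$samples)), 1e-6 * 5)

  inband <- sine_trace(1.2, rate = 30, duration = 30)
  y <- bandpass(inband)
  mid <- 150:750                               # avoid edge transients
  expect_equal(max(abs(y$samples[mid])), 1, tolerance = 0.05)

  t <- seq(0, 30 - 1 / 30, by = 1 / 30)
  stop_tr <- pulse_trace(sin(2 * pi * 5 * t), rate = 30)
  ys <- bandpass(stop_tr)
  expect_lt(max(abs(ys$samples[mid])), 10^(-20 / 20))  # > 20 dB down

  expect_error(bandpass(pulse_trace(rnorm(10), 30)), "too short")
  expect_error(bandpass(pulse_trace(rnorm(300), 4)), "too low")
})

test_that("band-pass is nearly idempotent on an in-band sinusoid", {
  tr <- sine_trace(1.5, rate = 30, duration = 30)
  y1 <- bandpass(tr)
  y2 <- bandpass(y1)
  mid <- 150:750
  expect_equal(y2$samples[mid], y1$samples[mid], tolerance = 0.01)
})

test_that("spectral HR is exact to one bin on clean sinusoids", {
  hr <- estimate_hr_window(sine_trace(1.2, 30, 10))
  expect_equal(hr, 72, tolerance = 0.6)        # one 0.01 Hz bin = 0.6 bpm
  expect_equal(estimate_hr_window(sine_trace(0.7, 30, 10)), 42,
               tolerance = 0.6)
  # dominant-peak rule
  t <- seq(0, 10 - 1 / 30, by = 1 / 30)
  two <- pulse_trace(3 * sin(2 * pi * t) + 0.5 * sin(2 * pi * 2 * t), 30)
  expect_equal(estimate_hr_window(two), 60, tolerance = 0.6)
  expect_error(estimate_hr_window(pulse_trace(rep(0, 300), 30)), "all-zero")
})

test_that("HR sweep across the pulse band stays within one bin", {
  for (bpm in seq(42, 150, by = 9)) {
    tr <- sine_trace(bpm / 60, rate = 30, duration = 10, phase = 0.7)
    expect_equal(estimate_hr_window(tr), bpm, tolerance = 0.6)
  }
})

test_that("window arithmetic matches the closed form", {
  expect_equal(nrow(windowed_hr(sine_trace(1.2, 30, 30))), 11)
  expect_equal(nrow(windowed_hr(sine_trace(1.2, 30, 10))), 1)
  expect_warning(empty <- windowed_hr(sine_trace(1.2, 30, 8)), "shorter")
  expect_equal(nrow(empty), 0)
  for (dur in seq(10, 120, by = 14)) {
    got <- nrow(windowed_hr(sine_trace(1.0, 30, dur)))
    expect_equal(got, floor((dur - 10) / 2) + 1)
  }
})

test_that("a frequency step shows up in the windowed series", {
  t1 <- seq(0, 15 - 1 / 30, by = 1 / 30)
  t2 <- seq(0, 15 - 1 / 30, by = 1 / 30)
  x <- c(sin(2 * pi * 1.2 * t1), sin(2 * pi * 1.6 * t2))
  hr <- windowed_hr(bandpass(pulse_trace(x, 30)))
  expect_equal(hr$bpm[1], 72, tolerance = 1.5)
  expect_equal(hr$bpm[nrow(hr)], 96, tolerance = 1.5)
})

test_that("agreement metrics reproduce hand-computed values", {
  pred <- rppgnet:::hr_series(data.frame(start_s = c(0, 2, 4),
                                         end_s = c(10, 12, 14),
                                         bpm = c(72, 80, 60)))
  ref <- rppgnet:::hr_series(data.frame(start_s = c(0, 2, 4),
                                        end_s = c(10, 12, 14),
                                        bpm = c(70, 80, 64)))
  m <- compute_metrics(pred, ref)
  expect_equal(m$mae_bpm, 2)
  expect_equal(m$rmse_bpm, sqrt(20 / 3), tolerance = 1e-12)
  expect_equal(m$pearson_r, cor(c(72, 80, 60), c(70, 80, 64)),
               tolerance = 1e-12)
  expect_equal(m$n_windows, 3)

  mm <- suppressWarnings(compute_metrics(pred, pred))
  expect_equal(mm$mae_bpm, 0)
  expect_equal(mm$rmse_bpm, 0)

  one <- rppgnet:::hr_series(pred[1, ])
  oneref <- rppgnet:::hr_series(ref[1, ])
  expect_warning(m1 <- compute_metrics(one, oneref), "undefined")
  expect_equal(m1$mae_bpm, 2)
  expect_equal(m1$rmse_bpm, 2)
  expect_true(is.na(m1$pearson_r))

  bad <- rppgnet:::hr_series(data.frame(start_s = c(1, 3, 5),
                                        end_s = c(11, 13, 15),
                                        bpm = c(1, 2, 3)))
  expect_error(compute_metrics(pred, bad), "not aligned")
  expect_error(compute_metrics(pred, rppgnet:::hr_series(ref[1:2, ])),
               "counts differ")
})

test_that("rmse dominates mae over random paired series", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    pred <- rppgnet:::hr_series(data.frame(start_s = 2 * (0:(n - 1)),
                                           end_s = 2 * (0:(n - 1)) + 10,
                                           bpm = runif(n, 50, 120)))
    ref <- rppgnet:::hr_series(data.frame(start_s = 2 * (0:(n - 1)),
                                          end_s = 2 * (0:(n - 1)) + 10,
                                          bpm = runif(n, 50, 120)))
    m <- suppressWarnings(compute_metrics(pred, ref))
    expect_gte(m$rmse_bpm, m$mae_bpm)
  }
})

test_that("Bland-Altman rows and limits behave", {
  pred <- rppgnet:::hr_series(data.frame(start_s = c(0, 2, 4),
                                         end_s = c(10, 12, 14),
                                         bpm = c(72, 80, 60)))
  ba0 <- bland_altman_table(pred, pred)
  expect_equal(ba0$table$diff_bpm, rep(0, 3))
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)

  shifted <- pred; shifted$bpm <- pred$bpm + 5
  ba5 <- bland_altman_table(rppgnet:::hr_series(shifted), pred)
  expect_equal(ba5$bias, 5)
  expect_equal(ba5$sd_diff, 0)
  expect_equal(nrow(ba5$table), 3)
})
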